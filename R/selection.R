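#' Atom selections
#'
#' A `Selection` is a labelled predicate over the atom table of a
#' [structure_model()]. On a given topology it resolves to a deterministic,
#' ordered atom index vector ([resolve_selection()]).
#'
#' @param predicate function taking the atom data.frame, returning a logical
#'   vector of length `n_atoms`
#' @param label short descriptive label
#' @return an object of class `Selection`
#' @export
selection <- function(predicate, label = "selection") {
  stopifnot(is.function(predicate))
  obj <- list(predicate = predicate, label = label)
  class(obj) <- "Selection"
  obj
}

#' @export
print.Selection <- function(x, ...) {
  cat(sprintf("Selection: %s\n", x$label)); invisible(x)
}

#' Resolve a selection to ordered atom indices
#' @param sel a `Selection`
#' @param model a `StructureModel`
#' @return integer vector of atom indices in file order
#' @export
resolve_selection <- function(sel, model) {
  if (is.numeric(sel)) return(as.integer(sel))
  stopifnot(inherits(sel, "Selection"))
  keep <- sel$predicate(model$atoms)
  if (!is.logical(keep) || length(keep) != n_atoms(model))
    stopf("selection predicate must return a logical of length n_atoms")
  which(keep)
}

#' Select atoms by chain, residue, atom name and/or element
#'
#' `NULL` filters match everything; `resid` may be a vector of residue
#' numbers (use `a:b` for ranges).
#'
#' @param chain,resid,name,element filters (NULL = no constraint)
#' @param label selection label
#' @export
select_atoms <- function(chain = NULL, resid = NULL, name = NULL,
                         element = NULL, label = NULL) {
  label <- label %||% paste0(
    if (!is.null(chain)) paste0("chain ", paste(chain, collapse = ",")) else "all chains",
    if (!is.null(resid)) paste0(" resid ", min(resid), "..", max(resid)) else "",
    if (!is.null(name)) paste0(" name ", paste(name, collapse = ",")) else ""
  )
  force(chain); force(resid); force(name); force(element)
  selection(function(a) {
    keep <- rep(TRUE, nrow(a))
    if (!is.null(chain)) keep <- keep & a$chain %in% chain
    if (!is.null(resid)) keep <- keep & a$resid %in% resid
    if (!is.null(name)) keep <- keep & a$name %in% name
    if (!is.null(element)) keep <- keep & a$element %in% element
    keep
  }, label = label)
}

#' @rdname select_atoms
#' @export
select_all <- function() selection(function(a) rep(TRUE, nrow(a)), "all atoms")

#' Combine selections
#' @param ... selections to combine
#' @param op `"or"` (union) or `"and"` (intersection)
#' @param label selection label
#' @export
select_combine <- function(..., op = c("or", "and"), label = NULL) {
  op <- match.arg(op)
  sels <- list(...)
  label <- label %||% paste(vapply(sels, `[[`, "", "label"), collapse = paste0(" ", op, " "))
  selection(function(a) {
    kk <- lapply(sels, function(s) s$predicate(a))
    Reduce(if (op == "or") `|` else `&`, kk)
  }, label = label)
}

protein_backbone_names <- c("N", "CA", "C", "O")

#' Protein backbone selection
#' @param chain optional chain filter
#' @export
select_backbone <- function(chain = NULL) {
  select_atoms(chain = chain, name = protein_backbone_names,
               label = paste("protein backbone", if (!is.null(chain)) paste(chain, collapse = ",") else ""))
}
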