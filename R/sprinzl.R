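#' Canonical Sprinzl position template
#'
#' The Sprinzl numbering convention labels tRNA positions 1-76 along the
#' cloverleaf, with optional D-loop residues 17a and 20a/20b and up to 27
#' variable-loop residues e1-e27 inserted between positions 45 and 46.
#' The template is the ordered label sequence of the maximal tRNA; shorter
#' molecules simply omit optional labels.
#'
#' @param n_e maximum number of variable-loop insertions to carry
#'   (default 27).
#' @return an object of class `sprinzl_template`: a list with `labels`
#'   (ordered character vector, maximal molecule), `core` (the 76 canonical
#'   labels), `optional_d` (D-loop optionals in insertion order) and
#'   `optional_e` (variable-loop labels in order).
#' @export
#' @examples
#' tpl <- sprinzl_template()
#' head(tpl$labels, 20)
sprinzl_template <- function(n_e = 27L) {
  stopifnot(n_e >= 0, n_e <= 27)
  core <- as.character(1:76)
  optional_d <- c("17a", "20a", "20b")
  optional_e <- if (n_e > 0) paste0("e", seq_len(n_e)) else character()
  labels <- c(
    as.character(1:17), "17a", "18", "19", "20", "20a", "20b",
    as.character(21:45), optional_e, as.character(46:76)
  )
  structure(
    list(labels = labels, core = core, optional_d = optional_d,
         optional_e = optional_e),
    class = "sprinzl_template"
  )
}

#' Assign Sprinzl labels to a family consensus
#'
#' Deterministic template walk: a 76-nt consensus maps 1:1 onto the
#' canonical labels 1-76; extra length is absorbed first by the optional
#' D-loop residues (17a, then 20a, 20b) and then by variable-loop residues
#' e1, e2, ... between positions 45 and 46. The split between D-loop and
#' variable-loop insertions can be forced with `n_dloop_extra` when the
#' isoacceptor architecture is known (e.g. long-variable-arm Ser/Leu
#' families with a canonical-length D-loop).
#'
#' @param family a [family_reference()] object.
#' @param template a [sprinzl_template()].
#' @param n_dloop_extra integer or `NULL`; number of the extra residues to
#'   place in the D-loop (0-3). Default `NULL` fills the D-loop first.
#' @return the family with its `numbering` field filled: a tibble with
#'   0-based `index` and character `label`, one row per consensus position.
#' @export
assign_sprinzl <- function(family, template = sprinzl_template(),
                           n_dloop_extra = NULL) {
  stopifnot(inherits(family, "family_reference"))
  len <- nchar(family$consensus)
  extra <- len - 76L
  if (extra < 0L) {
    stop("consensus of family '", family$family_id, "' is shorter (", len,
         " nt) than the canonical 76-nt Sprinzl core and cannot be numbered",
         call. = FALSE)
  }
  max_len <- 76L + length(template$optional_d) + length(template$optional_e)
  if (len > max_len) {
    stop("consensus of family '", family$family_id, "' (", len,
         " nt) exceeds the maximal Sprinzl template (", max_len, " nt)",
         call. = FALSE)
  }
  if (is.null(n_dloop_extra)) {
    n_d <- min(extra, length(template$optional_d))
  } else {
    stopifnot(n_dloop_extra >= 0, n_dloop_extra <= length(template$optional_d))
    n_d <- as.integer(n_dloop_extra)
  }
  n_e <- extra - n_d
  if (n_e < 0L || n_e > length(template$optional_e)) {
    stop("cannot place ", extra, " extra residues with n_dloop_extra = ",
         n_d, call. = FALSE)
  }
  keep <- c(
    template$core[1:17],
    if (n_d >= 1) "17a",
    as.character(18:20),
    if (n_d >= 2) "20a",
    if (n_d >= 3) "20b",
    as.character(21:45),
    if (n_e > 0) template$optional_e[seq_len(n_e)],
    as.character(46:76)
  )
  stopifnot(length(keep) == len)
  family$numbering <- tibble(index = 0:(len - 1L), label = keep)
  family
}

#' Translate between linear index and Sprinzl label
#'
#' @param family a numbered [family_reference()].
#' @param label,index Sprinzl label(s) / 0-based linear index(es).
#' @return `sprinzl_index()` returns 0-based indices (`NA` for absent
#'   labels); `sprinzl_label()` returns labels.
#' @export
sprinzl_index <- function(family, label) {
  stopifnot(inherits(family, "family_reference"), !is.null(family$numbering))
  family$numbering$index[match(as.character(label), family$numbering$label)]
}

#' @rdname sprinzl_index
#' @export
sprinzl_label <- function(family, index) {
  stopifnot(inherits(family, "family_reference"), !is.null(family$numbering))
  family$numbering$label[match(as.integer(index), family$numbering$index)]
}
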