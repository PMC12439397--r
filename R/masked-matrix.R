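#' Sparse expression matrix with an explicit missing-entry mask
#'
#' Distinguishes "measured" from "missing" entries: a stored entry is an
#' observed measurement (its value may legitimately be zero, e.g. after
#' per-patient centering), while an unstored entry is missing.  This is the
#' container produced by [mask_imputed()], where positions with zero raw
#' counts are declared missing so that values synthesized by an integration
#' method can never leak into downstream statistics.
#'
#' @param values A `dgCMatrix` whose stored entries are exactly the observed
#'   positions (explicit zeros permitted).
#' @param provenance Character flag recording how the values were produced.
#' @return A `masked_matrix` object.
#' @keywords internal
new_masked_matrix <- function(values, provenance = "normalized") {
  stopifnot(inherits(values, "dgCMatrix"))
  structure(list(values = values, provenance = provenance),
            class = "masked_matrix")
}

#' @export
print.masked_matrix <- function(x, ...) {
  v <- x$values
  cat("<masked_matrix> ", nrow(v), " genes x ", ncol(v), " cells, ",
      length(v@i), " observed entries (",
      format(100 * (1 - length(v@i) / (as.numeric(nrow(v)) * ncol(v))),
             digits = 3),
      "% missing), provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Observed-entry pattern of a masked matrix
#' @param m A `masked_matrix`.
#' @return An `lgCMatrix`, `TRUE` at observed positions.
#' @export
mm_observed <- function(m) {
  stopifnot(inherits(m, "masked_matrix"))
  v <- m$values
  methods::new("lgCMatrix", i = v@i, p = v@p,
               x = rep(TRUE, length(v@i)), Dim = v@Dim, Dimnames = v@Dimnames)
}

#' Dense view of a masked matrix with NA at missing entries
#' @param m A `masked_matrix`.
#' @return A base matrix with `NA` where entries are missing.
#' @export
mm_dense <- function(m) {
  stopifnot(inherits(m, "masked_matrix"))
  v <- m$values
  out <- matrix(NA_real_, nrow(v), ncol(v), dimnames = dimnames(v))
  if (length(v@i)) {
    j <- rep(seq_len(ncol(v)), diff(v@p))
    out[cbind(v@i + 1L, j)] <- v@x
  }
  out
}
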