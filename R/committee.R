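#' Committee force deviation
#'
#' Error estimate used for active-learning selection: for each configuration
#' the score is the maximum over atoms of the root-mean-square deviation of
#' the force vector across the committee about the committee mean,
#' `max_i sqrt(mean_m |f_im - <f_i>|^2)`.  The score is invariant under
#' adding a model-independent constant to all forces and under a global
#' rotation applied to every model jointly.
#'
#' @param force_sets list over models; each element a list over
#'   configurations of `n_atoms x 3` (or `n_atoms x k`) force matrices, as
#'   produced by [committee_force_sets()].
#' @return tibble with columns `config`, `deviation` (score) and `atom`
#'   (index of the maximising atom).
#' @export
committee_deviation <- function(force_sets) {
  if (length(force_sets) < 2) {
    abort("committee deviation is undefined for a single model")
  }
  force_sets <- lapply(force_sets, function(m) if (is.matrix(m)) list(m) else m)
  nc <- length(force_sets[[1]])
  out <- lapply(seq_len(nc), function(i) {
    fl <- lapply(force_sets, `[[`, i)
    fbar <- Reduce(`+`, fl) / length(fl)
    dev2 <- Reduce(`+`, lapply(fl, function(f) rowSums((f - fbar)^2))) / length(fl)
    rms <- sqrt(dev2)
    tibble(config = i, deviation = max(rms), atom = which.max(rms))
  })
  bind_rows(out)
}

#' Select configurations inside a deviation window
#'
#' Active-learning window semantics: scores at or above `lower` are
#' informative candidates, scores at or above `upper` are discarded as
#' unphysical.  Selection keeps `lower <= score < upper`, preserving order.
#'
#' @param scores numeric scores (or the tibble from [committee_deviation()]).
#' @param lower,upper window bounds (inclusive low, exclusive high).
#' @return integer indices of selected configurations.
#' @export
select_configs <- function(scores, lower, upper) {
  if (is.data.frame(scores)) scores <- scores$deviation
  which(scores >= lower & scores < upper)
}
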