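# Vectorized per-round cleavage probabilities for whole libraries. Agrees
# with the per-peptide cleavage_probability() (property-tested); used by the
# biopanning simulator where libraries reach 1e5+ unique sequences.

cleavage_probability_batch <- function(sequences, context, model) {
  n <- length(sequences)
  if (n == 0) return(numeric(0))
  L <- context$insert_length
  chars <- strsplit(sequences, "", fixed = TRUE)
  M <- matrix(unlist(chars), nrow = n, ncol = L, byrow = TRUE)
  up <- strsplit(context$upstream_arm, "", fixed = TRUE)[[1]]
  down <- strsplit(context$downstream_arm, "", fixed = TRUE)[[1]]
  n_up <- length(up); n_disp <- n_up + L + length(down)
  offs <- frame_offsets(model$frame)
  labels <- model$frame$labels
  scale <- model$site_efficiency_scale
  surv <- rep(1, n)   # prod(1 - p_site) accumulated over candidate offsets
  for (o in seq_len(L)) {
    cand <- which(M[, o] %in% model$admissible_p1)
    if (length(cand) == 0) next
    prod_w <- rep(scale, length(cand))
    for (j in seq_along(offs)) {
      pos <- n_up + o + offs[j]
      if (pos < 1 || pos > n_disp) {
        prod_w <- prod_w / 20
      } else if (pos <= n_up) {
        prod_w <- prod_w * model$weights[labels[j], up[pos]]
      } else if (pos > n_up + L) {
        prod_w <- prod_w * model$weights[labels[j], down[pos - n_up - L]]
      } else {
        prod_w <- prod_w * model$weights[labels[j], M[cand, pos - n_up]]
      }
    }
    surv[cand] <- surv[cand] * (1 - pmin(1, prod_w))
  }
  1 - surv
}
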