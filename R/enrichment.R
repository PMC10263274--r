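#' Simulate laminar enrichment of a rare tangle subpopulation
#'
#' Draws a synthetic population of tangles split into a common (non-ghost)
#' and a rare (ghost) group. Each non-ghost tangle lies in the layers of
#' interest (3 and 5) with probability `p_base`; ghost tangles have their
#' odds of lying there multiplied by `odds_ratio`. For each replicate the
#' 2x2 table (ghost status x layer group) is formed and the cross-product
#' odds ratio computed via [odds_ratio_ci()] (Haldane-Anscombe corrected
#' when a cell is empty). The estimator summary is the exponentiated mean
#' log odds ratio across replicates.
#'
#' @param n_nonghost,n_ghost Group sizes. Defaults 8050 and 57.
#' @param p_base Probability that a non-ghost tangle lies in layers 3 and 5.
#' @param odds_ratio Planted enrichment odds ratio for ghosts.
#' @param n_reps Number of seeded replicates.
#' @param seed Integer seed.
#' @return List with `or_hat` (exp mean log-OR), `reps` (tibble of per-rep
#'   tables and estimates) and the planted parameters.
#' @export
simulate_laminar_enrichment <- function(n_nonghost = 8050L, n_ghost = 57L,
                                        p_base = 0.45, odds_ratio = 7.9,
                                        n_reps = 200L, seed = 1L) {
  stopifnot(n_nonghost > 0, n_ghost > 0, p_base > 0, p_base < 1,
            odds_ratio > 0, n_reps > 0)
  odds_g <- p_base / (1 - p_base) * odds_ratio
  p_ghost <- odds_g / (1 + odds_g)
  reps <- with_private_seed(seed, {
    purrr::map_dfr(seq_len(n_reps), function(r) {
      a <- stats::rbinom(1, n_ghost, p_ghost)        # ghosts in layers 3&5
      b <- n_ghost - a
      cc <- stats::rbinom(1, n_nonghost, p_base)     # non-ghosts in 3&5
      dd <- n_nonghost - cc
      est <- odds_ratio_ci(a, b, cc, dd)
      tibble::tibble(rep = r, a = a, b = b, c = cc, d = dd,
                     or = est$or, corrected = est$corrected)
    })
  })
  list(or_hat = exp(mean(log(reps$or))),
       reps = reps,
       n_nonghost = n_nonghost, n_ghost = n_ghost,
       p_base = p_base, planted_or = odds_ratio, seed = seed)
}
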