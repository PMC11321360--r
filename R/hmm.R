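#' Forward algorithm over the frequency grid
#'
#' Runs the (optionally approximated) forward recursion
#' \deqn{F_{k,t} = e(t,k) \sum_l F_{l,t-1} P_{l,k}}
#' backward in time from a point mass at the modern frequency bin. Column
#' `t` of `F` represents `t - 1` generations before present. Each column is
#' rescaled to maximum 1 with the accumulated natural-log scale stored, so
#' likelihoods of long chains do not underflow. The likelihood assumes
#' uniform exit probabilities, \eqn{P(D|s) = \sum_k F_{k,T}}.
#'
#' @param models list of [transition_model()]s (one per (s, N) regime).
#' @param step_model integer vector of length `T`; entry `t` indexes the
#'   model carrying the chain from column `t - 1` to column `t` (entry 1 is
#'   ignored).
#' @param logE `K x T` matrix of natural-log emissions (column 1 ignored:
#'   the present-day column is the initial point mass). `-Inf` marks an
#'   impossible state.
#' @param init_bin bin index of the modern allele frequency.
#' @param one_derived logical length-`T` flags; steps at which exactly one
#'   derived lineage remains force the beam window down to bin 1 so the
#'   mixed-lineage coalescence at frequency 0 is never pruned away.
#' @param approx_b logical; prune each column to the expanded window holding
#'   99.9% of the previous column's mass (entries outside are exactly 0).
#' @param grid the [freq_grid()] the models were built on.
#' @param keep_matrix return the full `F` matrix (needed for posteriors);
#'   set `FALSE` when only the likelihood is required.
#' @return list with `loglik` (natural log; `-Inf` with `ok = FALSE` if the
#'   data are impossible under the chain), `F`, `logscale`, `ok`.
#' @export
run_forward <- function(models, step_model, logE, init_bin, grid,
                        one_derived = logical(ncol(logE)),
                        approx_b = TRUE, keep_matrix = FALSE) {
  Tn <- ncol(logE)
  stopifnot(length(step_model) == Tn, nrow(logE) == grid$K,
            init_bin >= 1, init_bin <= grid$K)
  if (length(one_derived) != Tn) stop("'one_derived' must have length T", call. = FALSE)
  .hmm_forward_cpp(lapply(models, `[[`, "P"),
                   as.integer(step_model), logE, as.integer(init_bin),
                   one_derived, approx_b, grid$x,
                   lapply(models, `[[`, "a"), lapply(models, `[[`, "b"),
                   keep_matrix)
}

#' Backward algorithm over the frequency grid
#'
#' Computes \eqn{B_{t,k} = \sum_l e(t+1,l) P_{k,l} B_{t+1,l}} with the last
#' column all ones, using the row bands of the banded transition model. No
#' beam pruning is applied to the backward pass. Per-column rescaling is
#' recorded as in [run_forward()]; for any `t`,
#' \eqn{\sum_k F_{k,t} B_{t,k}} (scales reattached) equals the forward
#' likelihood.
#'
#' @inheritParams run_forward
#' @return list with `B` (`K x T`, columns scaled to max 1) and `logscale`.
#' @export
run_backward <- function(models, step_model, logE, grid) {
  stopifnot(length(step_model) == ncol(logE), nrow(logE) == grid$K)
  .hmm_backward_cpp(lapply(models, `[[`, "P"),
                    as.integer(step_model), logE,
                    lapply(models, `[[`, "lo"), lapply(models, `[[`, "hi"))
}
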