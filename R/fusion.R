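#' Gated attention parameters
#'
#' Each modality is first linearly projected to a common dimension `D`
#' (the modalities' raw descriptor lengths differ), then scored. Two scoring
#' modes are provided:
#' \describe{
#'   \item{`per_modality`}{the canonical two-stage gate: importance score
#'     `s_i = tanh(w_i . h_i + b_i)` per modality, then softmax over the
#'     three scores;}
#'   \item{`concatenated`}{a single-stage alternative where each modality's
#'     score is a linear functional of the concatenated projected vector
#'     `[h_env, h_rgb, h_point]`, then softmax.}
#' }
#' Projections and score weights are Xavier-uniform from the seed.
#'
#' @param dims named lengths of the raw descriptors,
#'   e.g. `c(env = 64, rgb = 33, point = 22)`.
#' @param D common fusion dimension (default 32).
#' @param scoring_mode `"per_modality"` or `"concatenated"`.
#' @param seed integer seed.
#' @return Object of class `gate_params`.
#' @export
gate_params <- function(dims, D = 32,
                        scoring_mode = c("per_modality", "concatenated"),
                        seed = 1L) {
  scoring_mode <- match.arg(scoring_mode)
  stopifnot(D >= 1, length(dims) >= 2, !is.null(names(dims)))
  with_seed(child_seed(seed, "fusion"), {
    proj <- lapply(dims, function(d) xavier_uniform(c(D, d), d, D))
    W <- lapply(dims, function(d) as.numeric(xavier_uniform(c(D), D, 1)))
    b <- lapply(dims, function(d) 0)
    W_cat <- lapply(dims, function(d)
      as.numeric(xavier_uniform(c(D * length(dims)), D * length(dims), 1)))
    structure(list(proj = proj, W = W, b = b, W_cat = W_cat, D = D,
                   scoring_mode = scoring_mode, modalities = names(dims)),
              class = "gate_params")
  })
}

#' Project a raw modality descriptor to the fusion dimension
#'
#' @param h raw descriptor vector.
#' @param params a [gate_params()].
#' @param modality modality name present in `params$modalities`.
#' @return Numeric vector of length `params$D`.
#' @export
project_modality <- function(h, params, modality) {
  P <- params$proj[[modality]]
  if (is.null(P) || length(h) != ncol(P))
    edfm_stop("edfm_invalid_argument",
              "modality '%s': descriptor length %d does not match projection",
              modality, length(h))
  as.numeric(P %*% h)
}

#' Modality importance score
#'
#' `s_i = tanh(w_i . h_i + b_i)`, constrained to (-1, 1).
#'
#' @param h_proj projected modality vector (length D).
#' @param params a [gate_params()].
#' @param modality modality name.
#' @return Scalar score in (-1, 1).
#' @export
score_modality <- function(h_proj, params, modality) {
  w <- params$W[[modality]]
  if (is.null(w) || length(h_proj) != length(w))
    edfm_stop("edfm_invalid_argument", "dimension mismatch for '%s'", modality)
  tanh(sum(w * h_proj) + params$b[[modality]])
}

#' Softmax attention weights over modality scores
#'
#' Invariant under adding a constant to all scores; the result lies on the
#' probability simplex (non-negative, sums to 1).
#'
#' @param scores named numeric vector of per-modality scores.
#' @return Named numeric vector of weights summing to 1.
#' @export
attention_weights <- function(scores) {
  if (any(!is.finite(scores)))
    edfm_stop("edfm_invalid_argument", "scores must be finite")
  softmax(scores)
}

#' Fuse modality descriptors by gated attention
#'
#' Projects each modality to the common dimension, scores it, softmax-
#' normalizes the scores into attention weights and returns the weighted sum
#' `h_fusion = sum_i alpha_i h_i` together with the weights.
#'
#' If `masked = TRUE`, missing modalities (`NULL` entries) are dropped and
#' the softmax renormalizes over the present ones; otherwise a missing
#' modality is an error.
#'
#' @param bundle named list of raw descriptor vectors (one per modality in
#'   `params$modalities`).
#' @param params a [gate_params()].
#' @param masked renormalize over present modalities instead of failing.
#' @return List of class `fused_feature`: `h_fusion` (length D), `weights`
#'   (named, summing to 1) and `scores`.
#' @export
fuse <- function(bundle, params, masked = FALSE) {
  stopifnot(inherits(params, "gate_params"))
  mods <- params$modalities
  present <- mods[vapply(mods, function(m) !is.null(bundle[[m]]), logical(1))]
  if (!masked && length(present) < length(mods))
    edfm_stop("edfm_invalid_argument", "missing modality: %s",
              paste(setdiff(mods, present), collapse = ", "))
  if (length(present) == 0)
    edfm_stop("edfm_invalid_argument", "no modalities present")
  hp <- lapply(present, function(m) project_modality(bundle[[m]], params, m))
  names(hp) <- present
  scores <- if (params$scoring_mode == "per_modality") {
    vapply(present, function(m) score_modality(hp[[m]], params, m), numeric(1))
  } else {
    cat_vec <- unlist(hp[present], use.names = FALSE)
    vapply(present, function(m)
      sum(params$W_cat[[m]][seq_along(cat_vec)] * cat_vec), numeric(1))
  }
  names(scores) <- present
  alpha <- attention_weights(scores)
  h_fusion <- Reduce(`+`, Map(function(a, h) a * h, alpha, hp[present]))
  structure(list(h_fusion = h_fusion, weights = alpha, scores = scores),
            class = "fused_feature")
}

#' Per-growth-stage mean attention weights
#'
#' Averages daily attention weights within each growth stage, giving the
#' interpretable weight-evolution table (rows sum to 1 since averaging
#' preserves convexity). Empty stages are omitted with a warning.
#'
#' @param daily_weights data.frame or matrix of daily weights (one column
#'   per modality, rows = days) or a list of named weight vectors.
#' @param stage_labels character/factor of the same length as days.
#' @return data.frame with `stage`, `n_days` and one mean-weight column per
#'   modality.
#' @export
weight_trajectory <- function(daily_weights, stage_labels) {
  if (is.list(daily_weights) && !is.data.frame(daily_weights))
    daily_weights <- do.call(rbind, daily_weights)
  W <- as.matrix(daily_weights)
  stopifnot(nrow(W) == length(stage_labels))
  stages <- unique(as.character(stage_labels))
  rows <- lapply(stages, function(s) {
    m <- stage_labels == s
    if (!any(m)) {
      warning(sprintf("stage '%s' has no days: omitted", s))
      return(NULL)
    }
    data.frame(stage = s, n_days = sum(m),
               t(colMeans(W[m, , drop = FALSE])))
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
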