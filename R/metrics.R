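#' Sarle's bimodality coefficient
#'
#' `BiC = (m3^2 + 1) / (m4 + 3 (n-1)^2 / ((n-2)(n-3)))` with `m3` the sample
#' skewness and `m4` the sample excess kurtosis, both computed with the
#' population-style (biased) moment estimators. BiC lies in \[0, 1\]; values
#' above 5/9 (~0.556) indicate a bimodal distribution, which is the value a
#' uniform sample attains in the large-n limit; a Gaussian sample tends to
#' 1/3.
#'
#' @param samples Numeric vector with at least 4 values and nonzero
#'   variance.
#' @return The bimodality coefficient.
#' @export
bimodality_coefficient <- function(samples) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 4L) stop("need at least 4 samples (finite-sample correction)")
  mu <- mean(samples)
  v <- mean((samples - mu)^2)
  if (v == 0) stop("zero variance sample")
  m3 <- mean((samples - mu)^3) / v^1.5
  m4 <- mean((samples - mu)^4) / v^2 - 3
  (m3^2 + 1) / (m4 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Spearman rank correlation
#'
#' Spearman's rho with average ranks for ties; constant input yields `NA`.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return Correlation in \[-1, 1\], or `NA` if undefined.
#' @export
spearman_cc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}

#' Fractions of binarized motif state classes
#'
#' For a toggle switch, `F1` is the fraction of single-positive rows (`01`
#' or `10`), reported with the all-OFF (`f00`) and all-ON (`f11`)
#' complements. For a toggle triad the eight state strings are partitioned
#' into single-positive `F1` (`100`, `010`, `001`), double-positive `F2`
#' (`110`, `101`, `011`) and all-ON/all-OFF `F3` (`111`, `000`), which sum
#' to 1.
#'
#' @param states A `binarized_states` object or a character vector of state
#'   strings.
#' @return Named list of fractions: `F1`, `f00`, `f11` (switch) or `F1`,
#'   `F2`, `F3` (triad).
#' @export
state_fractions <- function(states) {
  s <- if (inherits(states, "binarized_states")) states$state else
    as.character(states)
  if (length(s) == 0L) stop("empty state table")
  width <- unique(nchar(s))
  if (length(width) != 1L || !(width %in% c(2L, 3L))) {
    stop("state strings must all be 2 (TS) or 3 (TT) characters")
  }
  n <- length(s)
  if (width == 2L) {
    list(F1 = sum(s %in% c("01", "10")) / n,
         f00 = sum(s == "00") / n,
         f11 = sum(s == "11") / n)
  } else {
    list(F1 = sum(s %in% c("100", "010", "001")) / n,
         F2 = sum(s %in% c("110", "101", "011")) / n,
         F3 = sum(s %in% c("111", "000")) / n)
  }
}

#' Bistable-to-monostable ratio of canonical toggle-switch states
#'
#' Ratio of the fraction of bistable parameter sets (exactly two stable
#' states) showing the canonical co-existing single-positive pair
#' \{01, 10\} to the fraction of monostable parameter sets showing a
#' single-positive state (01 or 10). Values above one mean bistable
#' parameter sets retain the canonical switch configuration more reliably
#' than monostable ones retain a single-positive state; the ratio declines
#' below one as incoming edges disrupt the co-existence of the two
#' single-positive states.
#'
#' Each model is classified by its set of *distinct motif states*: the
#' full-network stable states are projected onto the motif's ON/OFF string
#' first, so multistability among background nodes does not count against
#' the switch (an embedded model whose two network states both read `10`
#' on the motif is monostable as far as the switch is concerned).
#'
#' @param states Character vector of binarized 2-character motif states, one
#'   row per stable state.
#' @param model_id Integer vector assigning each row to its parameter set.
#' @param n_models Total number of parameter sets (unused by the ratio but
#'   kept for bookkeeping of empty models).
#' @return The B:M ratio, or `NA` if no monostable model exists. With no
#'   bistable models at all the numerator fraction is zero.
#' @export
bistable_monostable_ratio <- function(states, model_id,
                                      n_models = max(model_id)) {
  stopifnot(length(states) == length(model_id))
  by_model <- split(as.character(states), model_id)
  n_bi <- 0L
  n_bi_canon <- 0L
  n_mono <- 0L
  n_mono_sp <- 0L
  for (st in by_model) {
    st <- unique(st)  # distinct motif-state strings of this model
    if (length(st) == 2L) {
      n_bi <- n_bi + 1L
      if (setequal(st, c("01", "10"))) n_bi_canon <- n_bi_canon + 1L
    } else if (length(st) == 1L) {
      n_mono <- n_mono + 1L
      if (st %in% c("01", "10")) n_mono_sp <- n_mono_sp + 1L
    }
  }
  if (n_mono == 0L || n_mono_sp == 0L) return(NA_real_)
  num <- if (n_bi == 0L) 0 else n_bi_canon / n_bi
  num / (n_mono_sp / n_mono)
}

#' Maximum and minimum of the three pairwise triad correlations
#'
#' @param cc_ab,cc_bc,cc_ac Pairwise Spearman correlations.
#' @return Named list `MaxCC`, `MinCC`; both `NA` if any input is missing.
#' @export
max_min_cc <- function(cc_ab, cc_bc, cc_ac) {
  ccs <- c(cc_ab, cc_bc, cc_ac)
  if (any(!is.finite(ccs))) return(list(MaxCC = NA_real_, MinCC = NA_real_))
  list(MaxCC = max(ccs), MinCC = min(ccs))
}

#' Multiple linear regression of C on A and B
#'
#' Ordinary least squares plane `c ~ ACoeff * a + BCoeff * b + intercept`
#' quantifying how well the third triad node is explained by the other two.
#'
#' @param a,b Independent-variable vectors (steady states of A and B).
#' @param c Dependent-variable vector (steady states of C).
#' @return List with `ACoeff`, `BCoeff`, `intercept`, `R2`.
#' @export
mlr_fit <- function(a, b, c) {
  n <- length(c)
  if (n < 4L) stop("need at least 4 observations")
  X <- cbind(1, a, b)
  if (qr(X)$rank < 3L) stop("rank-deficient design (collinear a, b)")
  fit <- stats::lm.fit(X, c)
  cf <- fit$coefficients
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((c - mean(c))^2)
  list(ACoeff = unname(cf[2]), BCoeff = unname(cf[3]),
       intercept = unname(cf[1]), R2 = 1 - ss_res / ss_tot)
}

#' Resilience metrics of an embedded motif for one simulated ensemble
#'
#' Pools the ensemble's stable steady states, normalizes them by each
#' model's `G/k`, z-scores and binarizes them, and computes the per-network
#' metric record: Sarle's bimodality coefficient per motif node, pairwise
#' Spearman correlations, single/double-positive state fractions, and, for
#' a toggle switch, the bistable-to-monostable ratio, or, for a triad,
#' MaxCC/MinCC, F1/F2 and the multiple-linear-regression coefficients of C
#' on A and B (computed on the z-scored values).
#'
#' @param ensemble A `racipe_ensemble`.
#' @param nodes Node labels to treat as the motif (defaults to the
#'   topology's motif nodes). Passing background nodes gives the
#'   random-node control.
#' @param bic_scale Scale on which the bimodality coefficients and the
#'   regression are computed: `"log2"` (default; the scale on which the
#'   RACIPE tool family reports expression) or `"linear"`. Spearman
#'   correlations are rank-based and identical on both scales.
#' @param state_scale Scale whose z-scores are thresholded into ON/OFF
#'   state strings: `"linear"` (default; z-scores of the normalized values
#'   themselves) or `"log2"`.
#' @return One-row data frame of metrics.
#' @export
motif_metrics <- function(ensemble, nodes = NULL,
                          bic_scale = c("log2", "linear"),
                          state_scale = c("linear", "log2")) {
  stopifnot(inherits(ensemble, "racipe_ensemble"))
  bic_scale <- match.arg(bic_scale)
  state_scale <- match.arg(state_scale)
  if (is.null(nodes)) nodes <- ensemble$topology$motif$nodes
  y <- length(nodes)
  if (!(y %in% c(2L, 3L))) stop("metrics defined for 2 or 3 motif nodes")
  labels <- c("A", "B", "C")[seq_len(y)]  # positional labels, so control
  norm <- normalized_states(ensemble)     # records align with motif records
  vals <- if (bic_scale == "log2") log2(pmax(norm, .Machine$double.xmin))
    else norm
  bin <- zscore_binarize(norm, nodes,
                         log2_transform = state_scale == "log2")
  fr <- state_fractions(bin)

  bic <- vapply(nodes, function(nd) {
    tryCatch(bimodality_coefficient(vals[, nd]), error = function(e) NA_real_)
  }, numeric(1))
  names(bic) <- paste0("BiC_", labels)

  pairs <- utils::combn(seq_len(y), 2)
  cc <- apply(pairs, 2, function(pr) {
    spearman_cc(norm[, nodes[pr[1]]], norm[, nodes[pr[2]]])
  })
  names(cc) <- apply(pairs, 2, function(pr) {
    paste0("CC_", labels[pr[1]], labels[pr[2]])
  })

  rec <- c(as.list(bic), as.list(cc), fr)
  if (y == 2L) {
    rec$B_to_M <- bistable_monostable_ratio(bin$state, ensemble$model_id,
                                            ensemble$n_models)
  } else {
    mm <- max_min_cc(cc[[1]], cc[[3]], cc[[2]])  # AB, BC, AC ordering
    rec$MaxCC <- mm$MaxCC
    rec$MinCC <- mm$MinCC
    rec$F1_over_F2 <- if (rec$F2 > 0) rec$F1 / rec$F2 else NA_real_
    zv <- scale(vals[, nodes, drop = FALSE])
    ml <- tryCatch(mlr_fit(zv[, 1], zv[, 2], zv[, 3]),
                   error = function(e) list(ACoeff = NA_real_,
                                            BCoeff = NA_real_,
                                            intercept = NA_real_,
                                            R2 = NA_real_))
    rec$ACoeff <- ml$ACoeff
    rec$BCoeff <- ml$BCoeff
    rec$R2 <- ml$R2
  }
  as.data.frame(rec)
}
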