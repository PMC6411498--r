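# Vertex-wise multivariate group contrasts: Hotelling-type Mahalanobis
# statistic under pooled covariance, two-level permutation correction
# (vertex p-map, then map-level p_feature), directionality ratio maps, and
# p-value CDF diagnostics.

stack_features <- function(mms_list) {
  W <- nrow(mms_list[[1]]$features)
  d <- ncol(mms_list[[1]]$features)
  X <- array(0, c(length(mms_list), d, W))
  for (i in seq_along(mms_list)) {
    stopifnot(nrow(mms_list[[i]]$features) == W)
    X[i, , ] <- t(mms_list[[i]]$features)
  }
  X
}

#' Vertex-wise Mahalanobis statistic between two groups
#'
#' `M = (N_S N_T / (N_S + N_T)) (S.bar - T.bar)' Sigma^-1 (S.bar - T.bar)`
#' with `Sigma` the pooled covariance, shrunk toward its diagonal while its
#' condition number exceeds `cond_max`.
#'
#' @param groupA,groupB per-group feature arrays: `N x d x W` arrays, lists
#'   of `hm_mms`, or `N x d` matrices (single vertex).
#' @param cond_max condition-number ceiling before shrinkage.
#' @return numeric W-vector of statistics.
#' @export
mahalanobis_stat <- function(groupA, groupB, cond_max = 1e8) {
  norm_in <- function(g) {
    if (is.list(g) && inherits(g[[1]], "hm_mms")) return(stack_features(g))
    if (is.matrix(g)) return(array(g, c(nrow(g), ncol(g), 1L)))
    g
  }
  A <- norm_in(groupA); B <- norm_in(groupB)
  stopifnot(dim(A)[2] == dim(B)[2], dim(A)[3] == dim(B)[3])
  if (dim(A)[1] < 2L || dim(B)[1] < 2L)
    stop("each group needs at least 2 subjects", call. = FALSE)
  N <- dim(A)[1] + dim(B)[1]
  X <- array(0, c(N, dim(A)[2], dim(A)[3]))
  X[seq_len(dim(A)[1]), , ] <- A
  X[dim(A)[1] + seq_len(dim(B)[1]), , ] <- B
  mask <- c(rep(1L, dim(A)[1]), rep(0L, dim(B)[1]))
  as.vector(cpp_mahalanobis_map(as.vector(X), dim(X), mask, cond_max))
}

#' Two-level permutation test of a vertex-wise multivariate contrast
#'
#' Computes the observed Mahalanobis map, then `n_perm` group-size
#' preserving label permutations (identical across vertices within a
#' repetition). Uncorrected vertex p is `(#{M_perm >= M_obs} + 1) /
#' (n_perm + 1)`; the map-level correction compares the observed
#' `p_feature` (count of vertices with p < alpha) against each
#' permutation's own p_feature obtained from its leave-self-in rank in the
#' common permutation distribution.
#'
#' @param A,B group feature inputs as in [mahalanobis_stat()].
#' @param n_perm number of permutations (default 10,000).
#' @param alpha vertex-level threshold (default 0.05).
#' @param seed RNG seed.
#' @param strict_ties count only strictly greater permutation values
#'   (the default counts ties, which is conservative).
#' @param cond_max covariance condition ceiling.
#' @return An `hm_contrast`: per-vertex `M` and `p_uncorrected`,
#'   `p_feature`, `corrected_p`, significance `mask` (p < alpha),
#'   permutation settings and seed.
#' @export
permutation_pmap <- function(A, B, n_perm = 10000L, alpha = 0.05,
                             seed = 1L, strict_ties = FALSE,
                             cond_max = 1e8) {
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)", call. = FALSE)
  norm_in <- function(g) {
    if (is.list(g) && inherits(g[[1]], "hm_mms")) return(stack_features(g))
    if (is.matrix(g)) return(array(g, c(nrow(g), ncol(g), 1L)))
    g
  }
  Aa <- norm_in(A); Bb <- norm_in(B)
  nA <- dim(Aa)[1]; nB <- dim(Bb)[1]
  if (nA < 2L || nB < 2L) stop("each group needs >= 2 subjects", call. = FALSE)
  N <- nA + nB
  X <- array(0, c(N, dim(Aa)[2], dim(Aa)[3]))
  X[seq_len(nA), , ] <- Aa
  X[nA + seq_len(nB), , ] <- Bb
  set.seed(seed)
  perms <- matrix(0L, n_perm, N)
  for (p in seq_len(n_perm)) perms[p, sample.int(N, nA)] <- 1L
  obs_mask <- c(rep(1L, nA), rep(0L, nB))
  res <- cpp_perm_hotelling(as.vector(X), dim(X), obs_mask, perms, alpha,
                            strict_ties, cond_max)
  structure(list(M = as.vector(res$M),
                 p_uncorrected = as.vector(res$p_uncorrected),
                 p_feature = res$p_feature,
                 p_feature_perm = as.vector(res$p_feature_perm),
                 corrected_p = res$corrected_p,
                 mask = as.vector(res$p_uncorrected) < alpha,
                 alpha = alpha, n_perm = n_perm, seed = seed,
                 n = c(nA, nB)),
            class = "hm_contrast")
}

#' @export
print.hm_contrast <- function(x, ...) {
  cat(sprintf(
    "<hm_contrast> %d vs %d subjects, W = %d: p_feature = %d, corrected p = %.4g\n",
    x$n[1], x$n[2], length(x$M), x$p_feature, x$corrected_p))
  invisible(x)
}

#' Directionality ratio map of Jacobian determinants
#'
#' `R(k) = mean_i det J_1i(k) / mean_j det J_2j(k)` at every vertex in the
#' significance mask; `R > 1` marks atrophy of group 2 relative to group 1
#' at that vertex, `R < 1` expansion.
#'
#' @param detj_group1,detj_group2 `N x W` matrices of per-vertex Jacobian
#'   determinants (rows subjects), or lists of `hm_mms`.
#' @param mask logical W-vector (typically `contrast$mask`).
#' @return An `hm_ratio_map`: `R` (NA outside mask), `classification`
#'   ("atrophy"/"expansion"/NA), and the mask.
#' @export
ratio_map <- function(detj_group1, detj_group2, mask) {
  as_mat <- function(g) {
    if (is.list(g) && inherits(g[[1]], "hm_mms"))
      g <- do.call(rbind, lapply(g, function(m) m$detj))
    as.matrix(g)
  }
  D1 <- as_mat(detj_group1); D2 <- as_mat(detj_group2)
  stopifnot(ncol(D1) == ncol(D2), length(mask) == ncol(D1))
  if (any(D1 <= 0) || any(D2 <= 0))
    stop("det J must be positive everywhere", call. = FALSE)
  if (!any(mask)) {
    warning("empty significance mask; ratio map undefined everywhere")
    return(structure(list(R = rep(NA_real_, length(mask)),
                          classification = rep(NA_character_, length(mask)),
                          mask = mask), class = "hm_ratio_map"))
  }
  R <- rep(NA_real_, length(mask))
  R[mask] <- colMeans(D1[, mask, drop = FALSE]) /
             colMeans(D2[, mask, drop = FALSE])
  cls <- rep(NA_character_, length(mask))
  cls[mask] <- ifelse(R[mask] > 1, "atrophy", "expansion")
  structure(list(R = R, classification = cls, mask = mask),
            class = "hm_ratio_map")
}

#' Observed-vs-null p-value CDF curves
#'
#' For each contrast, sorted p-values against uniform quantiles (the null
#' diagonal); the deviation summary is the maximal vertical distance above
#' the diagonal.
#'
#' @param results a single `hm_contrast` or list of them (optionally named).
#' @return A list per contrast: `p_sorted`, `null_quantiles`, `deviation`.
#' @export
pvalue_cdf <- function(results) {
  if (inherits(results, "hm_contrast")) results <- list(results)
  lapply(results, function(r) {
    p <- sort(r$p_uncorrected)
    stopifnot(length(p) > 0)
    q <- seq_along(p) / length(p)
    list(p_sorted = p, null_quantiles = q,
         deviation = max(q - p))
  })
}

#' Permutation comparison of two volume samples
#'
#' Two-sided permutation p-value for the difference in group means with the
#' `(count + 1) / (n_perm + 1)` estimator.
#'
#' @param volumes_A,volumes_B numeric vectors (mm^3), each length >= 2.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return p-value in (0, 1].
#' @export
compare_volumes <- function(volumes_A, volumes_B, n_perm = 10000L, seed = 1L) {
  stopifnot(length(volumes_A) >= 2L, length(volumes_B) >= 2L)
  if (var(c(volumes_A, volumes_B)) == 0) {
    warning("degenerate volume samples (zero variance); p = 1")
    return(1)
  }
  pool <- c(volumes_A, volumes_B)
  nA <- length(volumes_A)
  obs <- abs(mean(volumes_A) - mean(volumes_B))
  set.seed(seed)
  ge <- 0L
  for (p in seq_len(n_perm)) {
    ia <- sample.int(length(pool), nA)
    d <- abs(mean(pool[ia]) - mean(pool[-ia]))
    if (d >= obs - 1e-12 * max(obs, 1)) ge <- ge + 1L
  }
  (ge + 1) / (n_perm + 1)
}
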