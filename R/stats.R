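# Group statistics: unpaired t-tests, supra-threshold cluster permutation
# tests on channel topographies (nonparametric mapping with family-wise
# error control via the permutation distribution of the maximal cluster
# statistic), and Spearman rank correlations.

#' Unpaired pooled-variance t-test
#'
#' Student t with pooled variance, `df = n_a + n_b - 2`, two-tailed p.
#' With zero pooled variance the statistic is 0 for equal means and signed
#' infinity otherwise.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @return List `(t, df, p)`.
#' @export
unpaired_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stopf("need n >= 2 per group")
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  d <- mean(a) - mean(b)
  t <- if (sp2 > 0) d / sqrt(sp2 * (1 / na + 1 / nb))
       else if (d == 0) 0 else sign(d) * Inf
  list(t = t, df = df, p = if (is.finite(t)) 2 * stats::pt(-abs(t), df) else 0)
}

#' t-test from group summary statistics
#'
#' `t = (mean_a - mean_b) / sqrt(se_a^2 + se_b^2)` with Welch-Satterthwaite
#' degrees of freedom; for checking published mean (+/- SE) tables.
#'
#' @param mean_a,se_a,n_a,mean_b,se_b,n_b group summaries (SE > 0).
#' @return List `(t, df, p)`.
#' @export
t_from_summary <- function(mean_a, se_a, n_a, mean_b, se_b, n_b) {
  if (se_a <= 0 || se_b <= 0) stopf("standard errors must be positive")
  t <- (mean_a - mean_b) / sqrt(se_a^2 + se_b^2)
  df <- (se_a^2 + se_b^2)^2 / (se_a^4 / (n_a - 1) + se_b^4 / (n_b - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Two-tailed Student critical value
#' @param alpha significance level.
#' @param df degrees of freedom.
#' @return Critical t such that `P(|T| > t) = alpha`.
#' @export
critical_t <- function(alpha = 0.05, df) stats::qt(1 - alpha / 2, df)

#' Spearman rank correlation
#'
#' Average ranks for ties; two-tailed p from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y numeric vectors (n >= 4).
#' @return List `(rho, p)`; `rho = NA` for constant input.
#' @export
spearman_corr <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stopf("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(t), n - 2))
}

#' Mean topography value over a cluster, per subject
#' @param topo subjects x channels matrix (colnames = channel labels).
#' @param cluster character vector of channel labels.
#' @return Per-subject numeric vector.
#' @export
cluster_mean <- function(topo, cluster) {
  if (!length(cluster)) stopf("empty cluster")
  miss <- setdiff(cluster, colnames(topo))
  if (length(miss)) stopf("cluster channels not in topography: %s",
                          paste(miss, collapse = ","))
  rowMeans(topo[, cluster, drop = FALSE])
}

# connected components of a channel subset under an adjacency list,
# split by sign; returns list of integer vectors (indices into `chan`)
supra_components <- function(chan, sgn, nb) {
  comps <- list()
  pos <- match(chan, chan)
  visited <- rep(FALSE, length(chan))
  for (s0 in seq_along(chan)) {
    if (visited[s0]) next
    stack <- s0; visited[s0] <- TRUE; comp <- s0
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      cand <- match(nb[[chan[v]]], chan)
      cand <- cand[!is.na(cand)]
      cand <- cand[!visited[cand] & sgn[cand] == sgn[v]]
      if (length(cand)) {
        visited[cand] <- TRUE
        stack <- c(stack, cand)
        comp <- c(comp, cand)
      }
    }
    # drop mixed-sign seeds: component retained only with uniform sign
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

# maximal cluster statistic of one t-map row
max_cluster_stat <- function(tv, thr, nb, stat) {
  chan <- which(abs(tv) > thr)
  if (!length(chan)) return(0)
  sgn <- sign(tv[chan])
  comps <- supra_components(chan, sgn, nb)
  m <- 0
  for (cp in comps) {
    v <- if (stat == "mass") sum(abs(tv[chan[cp]])) else length(cp)
    if (v > m) m <- v
  }
  m
}

# vectorized pooled-variance t-maps for many relabelings:
# X (n x C), Asel: n_perm x n 0/1 matrix selecting group A
perm_t_maps <- function(X, Asel, na, nb) {
  tot <- colSums(X); tot2 <- colSums(X^2)
  S <- Asel %*% X
  S2 <- Asel %*% (X^2)
  mA <- S / na
  mB <- sweep(-S, 2, tot, "+") / nb
  ssA <- S2 - S^2 / na
  ssB <- sweep(-S2, 2, tot2, "+") - sweep(-S, 2, tot, "+")^2 / nb
  sp2 <- (ssA + ssB) / (na + nb - 2)
  den <- sqrt(sp2 * (1 / na + 1 / nb))
  tm <- (mA - mB) / den
  tm[den == 0] <- 0
  tm
}

#' Supra-threshold cluster permutation test on channel topographies
#'
#' Channels whose observed pooled-variance t exceeds `t_thresh` in absolute
#' value are grouped into adjacency-connected clusters, separately for
#' positive and negative t.  Each cluster's statistic (mass = sum of |t|, or
#' size = channel count) is referred to the permutation distribution of the
#' maximal cluster statistic over random relabelings of group membership
#' (the original labeling is always included), giving family-wise-corrected
#' p-values.
#'
#' @param a,b subjects x channels matrices with identical channel columns.
#' @param adjacency an [build_adjacency()] graph over those channels.
#' @param t_thresh cluster-forming threshold; default the two-tailed critical
#'   t at alpha = 0.05 for `n_a + n_b - 2` degrees of freedom.
#' @param n_perm number of relabelings (>= 100 recommended; warned below).
#' @param seed RNG seed for the relabelings.
#' @param stat `"mass"` or `"size"`.
#' @param exact enumerate all relabelings when their number does not exceed
#'   `n_perm` (tiny designs only).
#' @return Data frame of clusters (`cluster_id, channels, n_channels, sign,
#'   stat, p`), possibly empty, with attributes `t_map` (observed per-channel
#'   t) and `null_max` (the permutation null).
#' @export
snpm_cluster_test <- function(a, b, adjacency, t_thresh = NULL,
                              n_perm = 8192, seed = 1,
                              stat = c("mass", "size"), exact = FALSE) {
  stat <- match.arg(stat)
  na <- nrow(a); nb <- nrow(b)
  if (na < 2L || nb < 2L) stopf("need >= 2 subjects per group")
  if (is.null(colnames(a))) colnames(a) <- adjacency$labels
  if (is.null(colnames(b))) colnames(b) <- colnames(a)
  if (!identical(colnames(a), colnames(b)))
    stopf("groups must share the same channel set")
  ord <- match(adjacency$labels, colnames(a))
  if (anyNA(ord)) stopf("adjacency channels missing from topographies")
  X <- rbind(a, b)[, ord, drop = FALSE]
  C <- ncol(X); n <- na + nb
  if (n_perm < 100) warning("n_perm < 100: corrected p-values are coarse")
  t_thresh <- t_thresh %||% critical_t(0.05, n - 2)
  if (t_thresh <= 0) stopf("t_thresh must be > 0")
  nb_list <- adjacency_list(adjacency)

  # relabeling matrix: rows select group A membership; row 1 = observed
  if (exact && choose(n, na) <= n_perm) {
    combs <- utils::combn(n, na)
    Asel <- matrix(0, ncol(combs), n)
    Asel[cbind(rep(seq_len(ncol(combs)), each = na), as.vector(combs))] <- 1
    # move the observed labeling first
    obs <- which(apply(Asel, 1, function(r) all(which(r == 1) == seq_len(na))))
    Asel <- rbind(Asel[obs, ], Asel[-obs, ])
  } else {
    Asel <- with_seed(seed, {
      M <- matrix(0, n_perm, n)
      M[1, seq_len(na)] <- 1
      for (r in 2:n_perm) M[r, sample.int(n, na)] <- 1
      M
    })
  }
  TM <- perm_t_maps(X, Asel, na, nb)
  t_obs <- TM[1, ]
  names(t_obs) <- adjacency$labels

  # null distribution of the max cluster statistic
  null_max <- numeric(nrow(TM))
  supra_any <- abs(TM) > t_thresh
  rows <- which(rowSums(supra_any) > 0)
  for (r in rows) null_max[r] <- max_cluster_stat(TM[r, ], t_thresh, nb_list, stat)

  # observed clusters
  chan <- which(abs(t_obs) > t_thresh)
  clusters <- list()
  if (length(chan)) {
    sgn <- sign(t_obs[chan])
    comps <- supra_components(chan, sgn, nb_list)
    for (cp in comps) {
      ch_idx <- chan[cp]
      s <- if (stat == "mass") sum(abs(t_obs[ch_idx])) else length(ch_idx)
      clusters[[length(clusters) + 1L]] <- data.frame(
        cluster_id = length(clusters) + 1L,
        channels = paste(adjacency$labels[ch_idx], collapse = ";"),
        n_channels = length(ch_idx), sign = unname(sgn[cp[1]]),
        stat = s, p = mean(null_max >= s))
    }
  }
  res <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(cluster_id = integer(), channels = character(),
               n_channels = integer(), sign = numeric(), stat = numeric(),
               p = numeric())
  res <- res[order(res$p, -res$stat), , drop = FALSE]
  res$cluster_id <- seq_len(nrow(res))
  rownames(res) <- NULL
  attr(res, "t_map") <- t_obs
  attr(res, "null_max") <- null_max
  attr(res, "t_thresh") <- t_thresh
  res
}
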