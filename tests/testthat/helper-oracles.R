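# Independent oracles, deliberately naive: these re-derive expected values by
# brute force and stay independent of the implementation paths they check.

# Wagner–Fischer dynamic programme, uniform costs
wf_levenshtein <- function(a, b) {
  a <- strsplit(a, "", fixed = TRUE)[[1]]
  b <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + (a[i] != b[j]))
  }
  d[n + 1, m + 1]
}

# exhaustive nearest-top plant, ties (up to fp noise) toward the smaller top
brute_force_nearest <- function(x, tops) {
  d <- abs(x - tops)
  cand <- which(d - min(d) < 1e-12)
  cand[which.min(tops[cand])]
}

# optimal one-to-one assignment by enumerating permutations (small n),
# maximising total IoU over pairs above the threshold
optimal_matching_size <- function(iou_mat, threshold) {
  np <- nrow(iou_mat); ng <- ncol(iou_mat)
  k <- min(np, ng)
  if (k == 0) return(list(n = 0L, total = 0))
  best_n <- 0L; best_total <- 0
  idx_p <- utils::combn(np, k, simplify = FALSE)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  for (ps in idx_p) {
    for (gs in perms(seq_len(ng))) {
      gs <- gs[seq_len(k)]
      vals <- iou_mat[cbind(ps, gs)]
      ok <- vals > threshold
      n <- sum(ok); tot <- sum(vals[ok])
      if (n > best_n || (n == best_n && tot > best_total)) {
        best_n <- n; best_total <- tot
      }
    }
  }
  list(n = best_n, total = best_total)
}

# largest horizontal gap between sorted word x-intervals
brute_force_largest_gap <- function(lefts, rights) {
  o <- order(lefts)
  lefts <- lefts[o]; rights <- rights[o]
  best <- c(size = -Inf, lo = NA, hi = NA)
  reach <- rights[1]
  for (i in seq_along(lefts)[-1]) {
    g <- lefts[i] - reach
    if (g > best["size"]) best <- c(size = g, lo = reach, hi = lefts[i])
    reach <- max(reach, rights[i])
  }
  best
}
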