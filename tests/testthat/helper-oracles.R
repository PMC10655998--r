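# Independent oracles used across the suite. These deliberately re-derive
# expected results by different means than the package implementation.

# rule-by-rule removal oracle, coded independently of filter_candidates():
# evaluates each printed removal rule on the raw statistics
oracle_removal_flags <- function(area, dark, mean_b, sd_b, fit, params) {
  out <- character(0)
  if (isTRUE(area < params$min_area_um2)) out <- c(out, "min_area")
  if (isTRUE(dark < params$min_dark_area_um2)) out <- c(out, "min_dark_area")
  if (isTRUE(mean_b > params$artifact_intensity_min_au) &&
      isTRUE(sd_b < params$artifact_sd_max_au)) out <- c(out, "uniform_dark")
  if (isTRUE(area < params$small_area_um2) &&
      isTRUE(fit < params$elliptic_fit_min)) out <- c(out, "non_elliptical")
  if (isTRUE(area > params$small_area_um2) &&
      isTRUE(dark / area > params$dark_fraction_max))
    out <- c(out, "dark_fraction")
  out
}

# build a candidate object directly from its statistics
make_candidate <- function(area, dark, mean_b, sd_b, fit, id = 1L) {
  list(id = id, pixels = cbind(row = 1L, col = 1L), n_px = 1L,
       area_um2 = area, dark_area_um2 = dark, mean_brown_au = mean_b,
       sd_brown_au = sd_b, elliptic_fit = fit, centroid = c(x = 0, y = 0))
}

# graph-based oracle for seeded growing: BFS components + explicit
# union over light bridges, independent of the C++ two-pass code
oracle_grow <- function(dark, light, connectivity = 8) {
  nr <- nrow(dark); nc <- ncol(dark)
  nbrs <- function(r, c) {
    if (connectivity == 8) {
      d <- expand.grid(dr = -1:1, dc = -1:1)
      d <- d[!(d$dr == 0 & d$dc == 0), ]
    } else d <- data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
    rr <- r + d$dr; cc <- c + d$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    cbind(rr[ok], cc[ok])
  }
  label_bfs <- function(mask) {
    lab <- matrix(0L, nr, nc); k <- 0L
    for (start in which(mask)) {
      r0 <- (start - 1L) %% nr + 1L; c0 <- (start - 1L) %/% nr + 1L
      if (lab[r0, c0] > 0) next
      k <- k + 1L
      queue <- list(c(r0, c0)); lab[r0, c0] <- k
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        nb <- nbrs(p[1], p[2])
        for (i in seq_len(nrow(nb))) {
          r <- nb[i, 1]; c <- nb[i, 2]
          if (mask[r, c] && lab[r, c] == 0L) {
            lab[r, c] <- k
            queue[[length(queue) + 1]] <- c(r, c)
          }
        }
      }
    }
    lab
  }
  dlab <- label_bfs(dark); llab <- label_bfs(light)
  nd <- max(dlab); nl <- max(llab)
  # adjacency between dark and light components
  parent <- seq_len(max(nd, 1L))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  light_seeds <- vector("list", nl)
  for (idx in which(dark)) {
    r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
    nb <- nbrs(r, c)
    for (i in seq_len(nrow(nb))) {
      l <- llab[nb[i, 1], nb[i, 2]]
      if (l > 0) light_seeds[[l]] <- union(light_seeds[[l]], dlab[r, c])
    }
  }
  for (l in seq_len(nl)) {
    s <- light_seeds[[l]]
    if (length(s) > 1) for (j in s[-1]) {
      a <- find(s[1]); b <- find(j)
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  # pixel partition: list of sorted pixel-index vectors, one per candidate
  roots <- if (nd > 0) vapply(seq_len(nd), find, 0L) else integer(0)
  groups <- list()
  for (idx in seq_len(nr * nc)) {
    r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
    root <- 0L
    if (dlab[r, c] > 0) root <- roots[dlab[r, c]]
    else if (llab[r, c] > 0) {
      s <- light_seeds[[llab[r, c]]]
      if (length(s)) root <- roots[s[1]]
    }
    if (root > 0) {
      key <- as.character(root)
      groups[[key]] <- c(groups[[key]], idx)
    }
  }
  unname(lapply(groups, sort))
}

# all permutations of 1..n (small n), recursively
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1)
  out <- list()
  for (p in sub) for (i in seq_len(n)) {
    q <- append(p, n, after = i - 1)
    out[[length(out) + 1]] <- q
  }
  out
}

# exact one-sided Spearman permutation p by direct R enumeration
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  rho_obs <- 1 - 6 * sum((rank(x) - rank(y))^2) / (n^3 - n)
  rhos <- vapply(all_perms(n), function(p)
    1 - 6 * sum((seq_len(n) - p)^2) / (n^3 - n), 0)
  if (rho_obs >= 0) mean(rhos >= rho_obs - 1e-12)
  else mean(rhos <= rho_obs + 1e-12)
}

# match rejected objects to artifact ground truth by nearest centroid
match_artifacts <- function(rejected_table, truth_artifacts) {
  vapply(seq_len(nrow(rejected_table)), function(i)
    which.min((truth_artifacts$x_px - rejected_table$centroid_x[i])^2 +
                (truth_artifacts$y_px - rejected_table$centroid_y[i])^2),
    0L)
}
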