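# Cluster-based permutation Spearman correlation between per-subject
# frequency differences and per-subject connectivity-change maps.

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks are used for ties; the two-sided p-value comes from the
#' t approximation with n - 2 degrees of freedom. A constant input has no
#' defined rank correlation and is returned as `NA` with `flag = TRUE`.
#'
#' @param x,y Numeric vectors of equal length (n >= 4).
#' @return List with `rho`, `p`, `n`, `flag`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, flag = TRUE))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- spearman_p(rho, n)
  list(rho = rho, p = p, n = n, flag = FALSE)
}

spearman_p <- function(rho, n) {
  r <- pmin(pmax(rho, -1), 1)
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  e1 <- ok & abs(abs(r) - 1) < 1e-12
  p[e1] <- 0
  mid <- ok & !e1
  tt <- r[mid] * sqrt((n - 2) / (1 - r[mid]^2))
  p[mid] <- 2 * stats::pt(-abs(tt), df = n - 2)
  p
}

# maps: subjects x freqs x times array -> subjects x cells matrix
maps_to_matrix <- function(maps) {
  d <- dim(maps)
  matrix(maps, nrow = d[1L], ncol = d[2L] * d[3L])
}

# column-wise Pearson correlation of pre-ranked map columns with a rank
# vector; the fast inner loop of the permutation engine.
rank_corr_cols <- function(Rc, rd) {
  rdc <- rd - mean(rd)
  s <- sqrt(sum(rdc^2))
  if (s == 0) return(rep(NA_real_, ncol(Rc)))
  as.numeric(crossprod(Rc, rdc)) / s
}

#' Cell-wise Spearman correlation map
#'
#' Correlates one per-subject scalar (e.g. the pre-stimulation
#' endogenous-exogenous frequency difference) with every (frequency, time)
#' cell of the per-subject connectivity-change maps. Subject identity is
#' checked between the two inputs; subjects whose map contains any missing
#' cell are dropped pairwise.
#'
#' @param diffs Named numeric vector, one value per subject.
#' @param maps Numeric array `subjects x freqs x times`; `dimnames[[1]]`
#'   must match `names(diffs)` (order included).
#' @return List with matrices `rho` and `p` (freqs x times), `n` (complete
#'   subjects), and `flagged` (cells with undefined correlation).
#' @export
correlation_map <- function(diffs, maps) {
  stopifnot(is.array(maps), length(dim(maps)) == 3L)
  if (!is.null(names(diffs)) && !is.null(dimnames(maps)[[1L]])) {
    if (!identical(names(diffs), dimnames(maps)[[1L]])) {
      stop("subject identifiers of `diffs` and `maps` disagree", call. = FALSE)
    }
  }
  if (length(diffs) != dim(maps)[1L]) {
    stop("`diffs` and `maps` have different subject counts", call. = FALSE)
  }
  complete <- stats::complete.cases(maps_to_matrix(maps)) & !is.na(diffs)
  if (sum(complete) < 4L) {
    stop("fewer than 4 subjects with complete maps", call. = FALSE)
  }
  maps <- maps[complete, , , drop = FALSE]
  diffs <- diffs[complete]
  n <- sum(complete)
  M <- maps_to_matrix(maps)
  R <- apply(M, 2L, rank)
  sds <- apply(R, 2L, stats::sd)
  Rc <- sweep(R, 2L, colMeans(R))
  Rc <- sweep(Rc, 2L, ifelse(sds > 0, sds * sqrt(n - 1), NA_real_), "/")
  rho <- rank_corr_cols(Rc, rank(diffs))
  p <- spearman_p(rho, n)
  dim(rho) <- dim(p) <- dim(maps)[2:3]
  list(rho = rho, p = p, n = n, flagged = is.na(rho),
       ranked = Rc, diffs = diffs)
}

#' Form spectro-temporal clusters of supra-threshold cells
#'
#' Cells with `p < alpha` are partitioned into connected components under
#' orthogonal (4-neighbour) adjacency on the (frequency bin, time bin) grid,
#' separately for positive and negative correlations; the mass of a cluster
#' is the sum of `|rho|` over its members.
#'
#' @param p,rho Matrices (freqs x times) from [correlation_map()].
#' @param alpha Cluster-forming threshold. Default 0.05.
#' @return List of clusters, each with `sign`, `cells` (two-column matrix of
#'   (freq bin, time bin) indices) and `mass`; ordered by decreasing mass.
#' @export
form_clusters <- function(p, rho, alpha = 0.05) {
  stopifnot(identical(dim(p), dim(rho)))
  supra <- !is.na(p) & p < alpha & !is.na(rho) & rho != 0
  cluster_components(supra, rho)
}

# connected components of supra-threshold cells (4-neighbour, same sign)
cluster_components <- function(supra, rho) {
  if (!any(supra)) return(list())
  nr <- nrow(supra); nc <- ncol(supra)
  lab <- matrix(0L, nr, nc)
  sgn <- sign(rho)
  clusters <- list()
  nxt <- 0L
  which_supra <- which(supra, arr.ind = TRUE)
  for (q in seq_len(nrow(which_supra))) {
    i <- which_supra[q, 1L]; j <- which_supra[q, 2L]
    if (lab[i, j] != 0L) next
    nxt <- nxt + 1L
    s <- sgn[i, j]
    # iterative flood fill over same-sign orthogonal neighbours
    stack <- matrix(c(i, j), ncol = 2L)
    cells <- matrix(integer(0), ncol = 2L)
    lab[i, j] <- nxt
    while (nrow(stack) > 0L) {
      cur <- stack[nrow(stack), , drop = FALSE]
      stack <- stack[-nrow(stack), , drop = FALSE]
      cells <- rbind(cells, cur)
      ci <- cur[1L]; cj <- cur[2L]
      nb <- rbind(c(ci - 1L, cj), c(ci + 1L, cj), c(ci, cj - 1L),
                  c(ci, cj + 1L))
      for (k in 1:4) {
        ni <- nb[k, 1L]; nj <- nb[k, 2L]
        if (ni >= 1L && ni <= nr && nj >= 1L && nj <= nc &&
            supra[ni, nj] && lab[ni, nj] == 0L && sgn[ni, nj] == s) {
          lab[ni, nj] <- nxt
          stack <- rbind(stack, c(ni, nj))
        }
      }
    }
    clusters[[nxt]] <- list(sign = if (s > 0) "positive" else "negative",
                            cells = unname(cells),
                            mass = sum(abs(rho[cells])))
  }
  clusters[order(vapply(clusters, `[[`, numeric(1), "mass"),
                 decreasing = TRUE)]
}

max_cluster_mass <- function(p, rho, alpha) {
  cl <- form_clusters(p, rho, alpha)
  if (length(cl) == 0L) 0 else cl[[1L]]$mass
}

# critical |rho| for p < alpha under the t-approximation; thresholding on
# |rho| is equivalent to thresholding the p-value and avoids computing p in
# the permutation loop.
rho_crit <- function(n, alpha) {
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(n - 2 + tc^2)
}

# all permutations of 1..n (n small), as a list
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

#' Cluster-based permutation correlation test
#'
#' Tests, at every (frequency, time) cell, the Spearman association between
#' a per-subject scalar and the per-subject connectivity-change maps, with
#' family-wise error control by cluster-based permutation: supra-threshold
#' cells (`p < alpha`) are clustered under 4-neighbour spectro-temporal
#' adjacency with positive and negative correlations kept separate, each
#' cluster's mass is the sum of `|rho|` over its cells, and each iteration
#' permutes the subject order of `diffs` (maps fixed) and records the
#' maximum cluster mass (0 when no cell survives). Observed clusters whose
#' mass strictly exceeds the 97.5th percentile of this null distribution are
#' flagged significant; a permutation p-value
#' `(1 + #\{null >= mass\}) / (1 + n_perm)` is reported alongside. When
#' fewer than `n_perm` distinct permutations exist, all `n!` permutations
#' are used instead.
#'
#' @param diffs Named per-subject values (see [correlation_map()]).
#' @param maps Array `subjects x freqs x times`.
#' @param n_perm Number of permutations (>= 100). Default 1000.
#' @param alpha Cluster-forming threshold. Default 0.05.
#' @param percentile Percentile of the max-mass null above which an
#'   observed cluster is significant. Default 97.5.
#' @param seed Seed for the permutation draw; fully reproducible.
#' @return An `imcoh_cluster_test`: `clusters` (with `significant` and
#'   `p_perm`), `null` (max-mass distribution), `threshold` (97.5th
#'   percentile), `rho`, `p`, `n`, `n_perm`, `alpha`, `seed`.
#' @export
permutation_test <- function(diffs, maps, n_perm = 1000, alpha = 0.05,
                             percentile = 97.5, seed = 1L) {
  if (n_perm < 100L) stop("`n_perm` must be at least 100", call. = FALSE)
  cm <- correlation_map(diffs, maps)
  n <- cm$n
  obs <- form_clusters(cm$p, cm$rho, alpha)
  dims <- dim(cm$rho)

  null <- with_seed(seed, {
    use_all <- n <= 7L && factorial(n) <= n_perm
    perms <- if (use_all) all_perms(n) else
      lapply(seq_len(n_perm), function(b) sample.int(n))
    rc <- rho_crit(n, alpha)
    rd <- rank(cm$diffs)
    vapply(perms, function(pp) {
      rho_b <- rank_corr_cols(cm$ranked, rd[pp])
      dim(rho_b) <- dims
      supra <- !is.na(rho_b) & abs(rho_b) > rc
      cl <- cluster_components(supra, rho_b)
      if (length(cl) == 0L) 0 else cl[[1L]]$mass
    }, numeric(1))
  })

  threshold <- stats::quantile(null, percentile / 100, names = FALSE)
  for (k in seq_along(obs)) {
    obs[[k]]$significant <- obs[[k]]$mass > threshold
    obs[[k]]$p_perm <- (1 + sum(null >= obs[[k]]$mass)) / (1 + length(null))
  }
  structure(list(clusters = obs, null = null, threshold = threshold,
                 rho = cm$rho, p = cm$p, n = n, n_perm = length(null),
                 alpha = alpha, seed = seed),
            class = "imcoh_cluster_test")
}

#' @export
print.imcoh_cluster_test <- function(x, ...) {
  cat(sprintf("<imcoh_cluster_test> n = %d subjects, %d permutations, alpha = %g\n",
              x$n, x$n_perm, x$alpha))
  cat(sprintf("  max-mass null 97.5th percentile: %.3f\n", x$threshold))
  if (length(x$clusters) == 0L) {
    cat("  no supra-threshold clusters\n")
  } else {
    show <- seq_len(min(6L, length(x$clusters)))
    for (k in show) {
      cl <- x$clusters[[k]]
      cat(sprintf("  cluster %d: %s, %d cells, mass %.3f, p_perm %.4f%s\n",
                  k, cl$sign, nrow(cl$cells), cl$mass, cl$p_perm,
                  if (cl$significant) " *" else ""))
    }
    if (length(x$clusters) > 6L) {
      cat(sprintf("  ... and %d smaller cluster(s)\n",
                  length(x$clusters) - 6L))
    }
  }
  invisible(x)
}

#' @export
summary.imcoh_cluster_test <- function(object, ...) {
  data.frame(
    cluster = seq_along(object$clusters),
    sign = vapply(object$clusters, `[[`, character(1), "sign"),
    n_cells = vapply(object$clusters, function(c) nrow(c$cells), integer(1)),
    mass = vapply(object$clusters, `[[`, numeric(1), "mass"),
    p_perm = vapply(object$clusters, `[[`, numeric(1), "p_perm"),
    significant = vapply(object$clusters, `[[`, logical(1), "significant"))
}

#' @export
plot.imcoh_cluster_test <- function(x, freqs = NULL, times = NULL, ...) {
  fa <- freqs %||% seq_len(nrow(x$rho))
  ta <- times %||% seq_len(ncol(x$rho))
  graphics::image(ta, fa, t(x$rho), xlab = "time bin", ylab = "frequency bin",
                  main = "Spearman rho (significant clusters outlined)",
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  zlim = c(-1, 1), ...)
  for (cl in x$clusters) {
    if (!isTRUE(cl$significant)) next
    graphics::points(ta[cl$cells[, 2L]], fa[cl$cells[, 1L]], pch = 0,
                     cex = 0.8)
  }
  invisible(x)
}
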