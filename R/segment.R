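#' k-means intensity thresholding parameters
#'
#' Clusters are sorted ascending by centroid; clusters with index below `t`
#' (0-based) are masked out. The defaults k = 3, t = 1 separate glass/adipose
#' background from low- and high-concentration tissue and remove only the
#' lowest cluster.
#'
#' @param k Number of clusters (>= 2). Default 3.
#' @param t Threshold cluster index, 0 <= t < k (0-based; t = 0 masks
#'   nothing). Default 1.
#' @param seed RNG seed for the k-means++ initialization. Default 0.
#' @param n_restarts Number of k-means++ restarts; best WCSS wins. Default 10.
#' @param max_iter Maximum Lloyd iterations per restart. Default 300.
#' @param tol Convergence tolerance on centroid movement. Default 1e-8.
#' @return An object of class `segment_params`.
#' @export
segment_params <- function(k = 3L, t = 1L, seed = 0L, n_restarts = 10L,
                           max_iter = 300L, tol = 1e-8) {
  k <- as.integer(k); t <- as.integer(t)
  if (k < 2L) stop("k must be >= 2")
  if (t < 0L || t >= k) stop("t must satisfy 0 <= t < k")
  structure(list(k = k, t = t, seed = as.integer(seed),
                 n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), tol = tol),
            class = "segment_params")
}

# run a block with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' 1-D k-means (Lloyd's algorithm with k-means++ initialization)
#'
#' Deterministic for a fixed seed; several k-means++ restarts are run and the
#' solution with the lowest within-cluster sum of squares is kept. Centroids
#' are returned sorted ascending, and each input value is assigned the
#' (0-based) index of its cluster in that order.
#'
#' @param values Numeric vector of finite values; must contain at least `k`
#'   distinct values.
#' @param k Number of clusters.
#' @param seed,n_restarts,max_iter,tol See [segment_params()].
#' @return List with `centroids` (ascending), `assignment` (0-based integer
#'   per value), and `wcss`.
#' @export
kmeans_1d <- function(values, k, seed = 0L, n_restarts = 10L,
                      max_iter = 300L, tol = 1e-8) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("values must be finite")
  k <- as.integer(k)
  ux <- unique(values)
  if (length(ux) < k)
    stop("need at least k = ", k, " distinct values, got ", length(ux))
  if (length(ux) == k) {
    cen <- sort(ux)
    asg <- match(values, cen) - 1L
    return(list(centroids = cen, assignment = asg, wcss = 0))
  }
  best <- NULL
  .with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      cen <- .kmeanspp_init(values, k)
      fit <- .lloyd_1d(values, cen, max_iter, tol)
      fit <- .polish_boundaries(values, fit)
      if (is.null(best) || fit$wcss < best$wcss) best <- fit
    }
  })
  best
}

# Deterministic refinement of the converged Lloyd solution. In 1-D every
# optimal clustering is contiguous in sorted order, so the solution is fully
# described by k-1 split points; coordinate descent over each split (holding
# the others fixed) escapes the boundary-misplacement local optima that
# Lloyd itself can converge to.
.polish_boundaries <- function(values, fit) {
  k <- length(fit$centroids)
  if (k < 2) return(fit)
  ord <- order(values)
  x <- values[ord]
  n <- length(x)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  ssq <- function(i, j) {
    s <- cs[j + 1] - cs[i]
    (cs2[j + 1] - cs2[i]) - s^2 / (j - i + 1)
  }
  # starts[q] = first sorted index of cluster q
  asg_sorted <- fit$assignment[ord]
  starts <- c(1L, which(diff(asg_sorted) != 0) + 1L)
  if (length(starts) != k) return(fit)   # degenerate; keep Lloyd's answer
  repeat {
    changed <- FALSE
    for (q in 2:k) {
      lo <- starts[q - 1] + 1L
      hi <- if (q < k) starts[q + 1] - 1L else n
      cand <- lo:hi
      cost <- vapply(cand, function(s)
        ssq(starts[q - 1], s - 1L) + ssq(s, hi), numeric(1))
      s_best <- cand[which.min(cost)]
      if (s_best != starts[q]) { starts[q] <- s_best; changed <- TRUE }
    }
    if (!changed) break
  }
  bnd <- starts[-1]
  asg_sorted <- rep(seq_len(k) - 1L, diff(c(starts, n + 1L)))
  centroids <- vapply(seq_len(k), function(q) {
    j <- if (q == k) n else starts[q + 1] - 1L
    mean(x[starts[q]:j])
  }, numeric(1))
  wcss <- sum(vapply(seq_len(k), function(q) {
    j <- if (q == k) n else starts[q + 1] - 1L
    ssq(starts[q], j)
  }, numeric(1)))
  if (wcss > fit$wcss) return(fit)
  asg <- integer(n)
  asg[ord] <- asg_sorted
  list(centroids = centroids, assignment = asg, wcss = wcss)
}

.kmeanspp_init <- function(values, k) {
  n <- length(values)
  cen <- numeric(k)
  cen[1] <- values[sample.int(n, 1)]
  d2 <- (values - cen[1])^2
  for (j in 2:k) {
    if (all(d2 == 0)) {
      cen[j] <- values[sample.int(n, 1)]
    } else {
      cen[j] <- values[sample.int(n, 1, prob = d2)]
    }
    d2 <- pmin(d2, (values - cen[j])^2)
  }
  cen
}

# Lloyd iterations in 1-D: assignment to nearest centroid is an interval
# lookup against the midpoints of the sorted centroids.
.lloyd_1d <- function(values, cen, max_iter, tol) {
  cen <- sort(cen)
  k <- length(cen)
  for (it in seq_len(max_iter)) {
    bounds <- (cen[-k] + cen[-1]) / 2
    asg <- findInterval(values, bounds) + 1L
    new_cen <- cen
    for (j in seq_len(k)) {
      sel <- asg == j
      if (any(sel)) {
        new_cen[j] <- mean(values[sel])
      } else {
        # re-seed an empty cluster at the point worst served by the others
        d2 <- vapply(values, function(v) min((v - new_cen[-j])^2), numeric(1))
        new_cen[j] <- values[which.max(d2)]
      }
    }
    new_cen <- sort(new_cen)
    if (max(abs(new_cen - cen)) < tol) { cen <- new_cen; break }
    cen <- new_cen
  }
  bounds <- (cen[-k] + cen[-1]) / 2
  asg <- findInterval(values, bounds) + 1L
  wcss <- sum((values - cen[asg])^2)
  list(centroids = cen, assignment = asg - 1L, wcss = wcss)
}

#' Background mask from per-element k-means intensity thresholding
#'
#' Runs [kmeans_1d()] on the flattened intensities of one element image,
#' sorts the clusters ascending, and masks every pixel belonging to a cluster
#' with index below `t`. The threshold is the minimum intensity assigned to
#' cluster `t`, so the mask is reproducible from that single scalar; pixels
#' exactly at the threshold are retained. Applied per element, independently
#' of all other elements.
#'
#' @param image An [element_image()] or numeric matrix.
#' @param params A [segment_params()].
#' @return A [pixel_mask()] with attributes `threshold` and `centroids`.
#' @export
kmeans_threshold <- function(image, params = segment_params()) {
  stopifnot(inherits(params, "segment_params"))
  dat <- .image_data(image)
  if (!all(is.finite(dat))) stop("image must be finite")
  if (length(unique(as.vector(dat))) < params$k)
    stop("image is degenerate (fewer than k distinct intensities); ",
         "no k-means threshold exists")
  fit <- kmeans_1d(as.vector(dat), params$k, seed = params$seed,
                   n_restarts = params$n_restarts,
                   max_iter = params$max_iter, tol = params$tol)
  thr <- if (params$t == 0L) min(dat)
         else min(as.vector(dat)[fit$assignment == params$t])
  m <- pixel_mask(matrix(dat >= thr, nrow = nrow(dat)))
  attr(m, "threshold") <- thr
  attr(m, "centroids") <- fit$centroids
  m
}

#' Combine two congruent masks
#'
#' @param mask_a,mask_b [pixel_mask()] objects of identical shape.
#' @param mode `"and"` (intersection) or `"or"` (union).
#' @return A [pixel_mask()].
#' @export
combine_masks <- function(mask_a, mask_b, mode = c("and", "or")) {
  mode <- match.arg(mode)
  stopifnot(inherits(mask_a, "pixel_mask"), inherits(mask_b, "pixel_mask"))
  if (!.congruent(mask_a$data, mask_b$data))
    stop("masks are not congruent: ",
         paste(dim(mask_a$data), collapse = "x"), " vs ",
         paste(dim(mask_b$data), collapse = "x"))
  pixel_mask(if (mode == "and") mask_a$data & mask_b$data
             else mask_a$data | mask_b$data)
}
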