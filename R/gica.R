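# Temporal-concatenation group spatial ICA: two-stage PCA reduction,
# natural-gradient Infomax with bootstrap stability selection (repeated
# runs + average-linkage clustering of the pooled estimates), and
# dual-regression back-projection of subject time courses and maps.

#' PCA reduction and whitening
#'
#' Projects the rows of `x` (variables x observations) onto the top-`k`
#' principal subspace and whitens, so the reduced rows have unit variance
#' and zero mutual correlation.
#'
#' @param x Numeric matrix, rows = variables, columns = observations.
#' @param k Target dimension.
#' @param demean Subtract row means first.
#' @return Object of class `reduced_data`: list with `reduced` (k x m),
#'   `whitener` (k x n), `dewhitener` (n x k, right-inverse of the
#'   whitener on the retained subspace), `values` (all eigenvalues),
#'   `retained` (retained-variance fraction), `row_means`.
#' @export
pca_reduce <- function(x, k, demean = TRUE) {
  stopifnot(is.matrix(x), all(is.finite(x)))
  n <- nrow(x)
  if (k > min(dim(x))) stop("k = ", k, " exceeds min(dim(x)) = ", min(dim(x)))
  mu <- if (demean) rowMeans(x) else rep(0, n)
  xc <- x - mu
  C <- tcrossprod(xc) / (ncol(x) - 1)
  ee <- eigen(C, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  rank <- sum(vals > max(vals) * 1e-10)
  if (k > rank)
    stop("input has numerical rank ", rank, "; cannot retain k = ", k,
         " components")
  E <- ee$vectors[, seq_len(k), drop = FALSE]
  d <- sqrt(vals[seq_len(k)])
  whitener <- t(E) / d
  structure(list(reduced = whitener %*% xc,
                 whitener = whitener,
                 dewhitener = E * rep(d, each = n),
                 values = vals,
                 retained = sum(vals[seq_len(k)]) / sum(vals),
                 row_means = mu, k = k),
            class = "reduced_data")
}

symmetric_decorrelate <- function(W) {
  e <- eigen(tcrossprod(W), symmetric = TRUE)
  e$vectors %*% (t(e$vectors) / sqrt(pmax(e$values, .Machine$double.eps))) %*% W
}

#' Natural-gradient Infomax unmixing
#'
#' Square ICA on whitened data using the natural-gradient Infomax rule with
#' the logistic nonlinearity, an annealed learning rate, and symmetric
#' decorrelation of the unmixing matrix after each step (the whitened-space
#' optimum is a rotation, so the constraint loses nothing and keeps source
#' estimates exactly uncorrelated). On weight explosion the learning rate is
#' halved and the fit restarted, up to `max_restarts` times.
#'
#' @param z Whitened matrix (k x m), rows uncorrelated with unit variance.
#' @param seed Optional seed for the random orthonormal initialization.
#' @param lr Initial learning rate.
#' @param anneal Per-iteration learning-rate decay factor.
#' @param max_iter Maximum iterations.
#' @param tol Convergence tolerance on the Frobenius norm of the weight
#'   change.
#' @param max_restarts Restarts allowed after divergence.
#' @return List with `W` (unmixing matrix, orthonormal rows), `iterations`,
#'   `converged`, `lr_final`.
#' @export
infomax_unmix <- function(z, seed = NULL, lr = 0.5, anneal = 0.9995,
                          max_iter = 512, tol = 1e-7, max_restarts = 5) {
  k <- nrow(z)
  m <- ncol(z)
  if (!is.null(seed)) set.seed(seed)
  W0 <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
  I_k <- diag(k)
  for (attempt in 0:max_restarts) {
    W <- W0
    eta <- lr / 2^attempt
    converged <- FALSE
    diverged <- FALSE
    it <- 0
    while (it < max_iter) {
      it <- it + 1
      u <- W %*% z
      y <- 1 / (1 + exp(-u))
      grad <- (I_k + ((1 - 2 * y) %*% t(u)) / m) %*% W
      W_new <- W + eta * grad
      if (!all(is.finite(W_new)) || max(abs(W_new)) > 1e6) {
        diverged <- TRUE
        break
      }
      W_new <- symmetric_decorrelate(W_new)
      delta <- sqrt(sum((W_new - W)^2))
      W <- W_new
      eta <- eta * anneal
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    if (!diverged)
      return(list(W = W, iterations = it, converged = converged,
                  lr_final = eta, restarts = attempt))
  }
  stop("infomax_unmix diverged after ", max_restarts, " learning-rate restarts")
}

#' Stability-selected ICA (repeated runs + clustering)
#'
#' Runs Infomax `n_runs` times on bootstrap-resampled, randomly initialized
#' copies of the whitened data, pools all `n_runs * k` component estimates,
#' computes their pairwise similarity, clusters them by average-linkage
#' agglomeration into `model_order` clusters, and returns each cluster's
#' centrotype (the estimate with maximal average within-cluster similarity)
#' together with a stability index: mean intra-cluster minus mean
#' extra-cluster similarity.
#'
#' @param z Whitened matrix (k x m).
#' @param n_runs Number of repeated ICA runs (>= 2).
#' @param model_order Number of clusters / selected components.
#' @param bootstrap Resample observations with replacement per run.
#' @param randomize_init Randomize the Infomax initialization per run.
#'   With both `bootstrap` and `randomize_init` off, all runs are identical
#'   and every stability index equals 1.
#' @param seed Seed controlling resampling and initializations.
#' @param similarity `"map"` (default): absolute Pearson correlation between
#'   source estimates on the full data; `"timecourse"`: the same on
#'   time-course estimates expanded through `expand`.
#' @param expand Matrix mapping whitened-space mixing columns to full
#'   (concatenated) time courses; required for `similarity = "timecourse"`.
#' @param ... Passed to [infomax_unmix()].
#' @return List with `W` (model_order x k selected unmixing rows), `maps`
#'   (model_order x m source estimates), `stability_iq`, `cluster_sizes`,
#'   `n_empty_merged`, `similarity`.
#' @export
icasso_select <- function(z, n_runs = 10, model_order = nrow(z),
                          bootstrap = TRUE, randomize_init = TRUE, seed = 1,
                          similarity = c("map", "timecourse"),
                          expand = NULL, ...) {
  stopifnot(n_runs >= 2)
  similarity <- match.arg(similarity)
  if (similarity == "timecourse" && is.null(expand))
    stop("similarity = 'timecourse' requires an `expand` matrix")
  k <- nrow(z)
  m <- ncol(z)
  Ws <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(derive_seed(seed, 300, r))
    idx <- if (bootstrap) sample.int(m, m, replace = TRUE) else seq_len(m)
    init_seed <- if (randomize_init) derive_seed(seed, 400, r) else derive_seed(seed, 400, 1)
    Ws[[r]] <- infomax_unmix(z[, idx, drop = FALSE], seed = init_seed, ...)$W
  }
  U <- do.call(rbind, Ws)                    # (n_runs*k) x k pooled unmixing
  est <- if (similarity == "map") U %*% z else U %*% t(expand)
  S <- abs(stats::cor(t(est)))
  S[!is.finite(S)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - S), method = "average")
  cl <- stats::cutree(hc, k = model_order)

  W_sel <- matrix(0, model_order, k)
  iq <- numeric(model_order)
  sizes <- integer(model_order)
  for (c_id in seq_len(model_order)) {
    members <- which(cl == c_id)
    sizes[c_id] <- length(members)
    Sin <- S[members, members, drop = FALSE]
    centro <- members[which.max(rowMeans(Sin))]
    W_sel[c_id, ] <- U[centro, ]
    intra <- if (length(members) > 1)
      mean(Sin[upper.tri(Sin)]) else 1
    extra <- if (length(members) < nrow(S))
      mean(S[members, -members, drop = FALSE]) else 0
    iq[c_id] <- min(1, max(0, intra - extra))
  }
  list(W = W_sel, maps = W_sel %*% z, stability_iq = iq,
       cluster_sizes = sizes, n_empty_merged = 0L, similarity = similarity)
}

#' Dual-regression back-projection
#'
#' Estimates subject-specific component time courses and maps for a set of
#' group spatial maps: each volume (time point) is regressed on the group
#' maps, giving the subject time courses; the subject data are then
#' regressed on those time courses, giving subject maps.
#'
#' @param maps V x K matrix of group spatial maps.
#' @param x T x V subject/run data matrix on the same voxel grid.
#' @param max_condition Rejection bound on the condition number of the
#'   map Gram matrix.
#' @return List with `timecourses` (T x K) and `maps` (V x K).
#' @export
back_project <- function(maps, x, max_condition = 1e8) {
  stopifnot(ncol(x) == nrow(maps))
  G <- crossprod(maps)
  kap <- kappa(G, exact = TRUE)
  if (kap > max_condition)
    stop("group maps are near-collinear (condition number ",
         format(kap, digits = 3), "); back-projection rejected")
  xc <- sweep(x, 2, colMeans(x))
  tc <- xc %*% maps %*% solve(G)
  M <- t(solve(crossprod(tc), crossprod(tc, xc)))
  list(timecourses = tc, maps = M)
}

#' Z-score and threshold a spatial map
#'
#' Standardizes a map by the mean and sd of its in-mask voxels, applies the
#' standardization to every voxel, and zeroes voxels with |z| below the
#' threshold.
#'
#' @param map Numeric vector or array.
#' @param mask Logical mask of the same length (reference voxels).
#' @param threshold Absolute z threshold.
#' @return List with `z` (full thresholded z map) and `supra` (indices of
#'   suprathreshold voxels).
#' @export
zscore_map <- function(map, mask, threshold = 2) {
  map <- as.vector(map)
  mask <- as.vector(mask)
  stopifnot(length(map) == length(mask), sum(mask) > 0)
  mu <- mean(map[mask])
  s <- stats::sd(map[mask])
  if (!is.finite(s) || s == 0) {
    warning("zero-variance map; returning all zeros")
    return(list(z = rep(0, length(map)), supra = integer(0)))
  }
  z <- (map - mu) / s
  zt <- ifelse(abs(z) > threshold, z, 0)
  list(z = zt, supra = which(abs(z) > threshold))
}

#' Group ICA of a multi-subject cohort
#'
#' Full temporal-concatenation pipeline: per-run PCA reduction to
#' `subject_k` dimensions, concatenation, group-stage reduction/whitening
#' to `model_order`, stability-selected Infomax, a sign convention (each
#' map flipped so its skewness is positive), and dual-regression
#' back-projection per subject/run.
#'
#' @param data Nested list `data[[subject]][[run]]` of T x V matrices.
#' @param model_order Number of group components.
#' @param subject_k First-stage dimension (default 1.5 x model order).
#' @param n_runs ICASSO repetitions.
#' @param seed Seed for resampling/initialization.
#' @param trim_volumes Initial volumes dropped from each run before
#'   decomposition and back-projection.
#' @param ... Passed to [icasso_select()].
#' @return Object of class `component_set`: list with `group_maps` (V x K,
#'   z-scored over analyzed voxels), `raw_maps`, `subject_timecourses`
#'   (nested list of T x K), `subject_maps`, `stability_iq`, `retained`
#'   (variance fractions), `model_order`, `n_subjects`, `n_runs`.
#' @export
group_ica <- function(data, model_order = 30,
                      subject_k = ceiling(1.5 * model_order),
                      n_runs = 10, seed = 1, trim_volumes = 0, ...) {
  n_sub <- length(data)
  n_run <- length(data[[1]])
  V <- ncol(data[[1]][[1]])
  stage1 <- list()
  blocks <- list()
  i <- 0
  for (s in seq_len(n_sub)) for (r in seq_len(n_run)) {
    i <- i + 1
    x <- data[[s]][[r]]
    if (trim_volumes > 0) x <- x[-seq_len(trim_volumes), , drop = FALSE]
    red <- pca_reduce(x, subject_k)        # rows = time points: reduce time
    stage1[[i]] <- red
    blocks[[i]] <- red$reduced             # subject_k x V
  }
  xg <- do.call(rbind, blocks)
  red2 <- pca_reduce(xg, model_order)
  z <- red2$reduced                        # model_order x V

  # expansion matrix for time-course similarity: concatenated T_total x n_pc
  expand <- NULL
  dots <- list(...)
  if (identical(dots$similarity, "timecourse")) {
    n_pc <- nrow(xg)
    Tl <- nrow(stage1[[1]]$dewhitener)
    expand <- matrix(0, Tl * length(stage1), n_pc)
    for (j in seq_along(stage1)) {
      rows <- (j - 1) * Tl + seq_len(Tl)
      cols <- (j - 1) * subject_k + seq_len(subject_k)
      expand[rows, cols] <- stage1[[j]]$dewhitener
    }
    # map whitened-space mixing columns to concatenated full time courses
    expand <- expand %*% red2$dewhitener
  }

  sel <- icasso_select(z, n_runs = n_runs, model_order = model_order,
                       seed = seed, expand = expand, ...)
  raw_maps <- t(sel$maps)                  # V x K

  # sign convention: positive spatial skewness
  for (k in seq_len(model_order)) {
    mk <- raw_maps[, k]
    sk <- mean((mk - mean(mk))^3)
    if (sk < 0) raw_maps[, k] <- -mk
  }
  zmaps <- apply(raw_maps, 2, function(m) (m - mean(m)) / stats::sd(m))

  tcs <- vector("list", n_sub)
  smaps <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    tcs[[s]] <- vector("list", n_run)
    smaps[[s]] <- vector("list", n_run)
    for (r in seq_len(n_run)) {
      x <- data[[s]][[r]]
      if (trim_volumes > 0) x <- x[-seq_len(trim_volumes), , drop = FALSE]
      bp <- back_project(zmaps, x)
      tcs[[s]][[r]] <- bp$timecourses
      smaps[[s]][[r]] <- bp$maps
    }
  }
  structure(list(group_maps = zmaps, raw_maps = raw_maps,
                 subject_timecourses = tcs, subject_maps = smaps,
                 stability_iq = sel$stability_iq,
                 cluster_sizes = sel$cluster_sizes,
                 retained = c(stage1 = mean(vapply(stage1, `[[`, 0, "retained")),
                              group = red2$retained),
                 model_order = model_order, n_subjects = n_sub, n_runs = n_run,
                 trim_volumes = trim_volumes),
            class = "component_set")
}

#' Match estimated components to reference maps/time courses
#'
#' Greedy assignment by descending absolute spatial correlation.
#'
#' @param est_maps V x K estimated maps.
#' @param true_maps V x J reference maps.
#' @return data.frame with `truth`, `component`, `spatial_r`.
#' @export
match_components <- function(est_maps, true_maps) {
  R <- abs(stats::cor(true_maps, est_maps))
  J <- nrow(R)
  out <- data.frame(truth = seq_len(J), component = NA_integer_,
                    spatial_r = NA_real_)
  taken <- logical(ncol(R))
  for (i in order(apply(R, 1, max), decreasing = TRUE)) {
    j <- order(R[i, ], decreasing = TRUE)
    j <- j[!taken[j]][1]
    out$component[i] <- j
    out$spatial_r[i] <- R[i, j]
    taken[j] <- TRUE
  }
  out
}
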