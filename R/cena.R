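#' Pooled min-max feature matrix for cluster exchange analysis
#'
#' Builds the (region, epoch) x factor matrix of normalized width, height
#' and NDVI. Min-max scaling is computed over the pooled multi-epoch data so
#' that the same physical value maps to the same normalized value in every
#' epoch — required for cluster labels to be comparable across epochs. A
#' factor that is constant across the pool maps to 0.
#'
#' @param records data.frame with `region_id`, `epoch`, `amw_m`, `ach_m`,
#'   `ndvi`, covering at least two epochs.
#' @return numeric matrix with columns `amw`, `ach`, `ndvi` in `[0, 1]` and
#'   attributes `region_id` and `epoch` aligned with its rows.
#' @export
normalize_features <- function(records) {
  need <- c("region_id", "epoch", "amw_m", "ach_m", "ndvi")
  if (!all(need %in% names(records)))
    stop("validation error: records must have columns ",
         paste(need, collapse = ", "))
  if (length(unique(records$epoch)) < 2L)
    stop("validation error: need records for at least two epochs")
  raw <- as.matrix(records[, c("amw_m", "ach_m", "ndvi")])
  X <- apply(raw, 2L, function(v) {
    rng <- range(v)
    if (diff(rng) > 0) (v - rng[1]) / diff(rng) else rep(0, length(v))
  })
  colnames(X) <- c("amw", "ach", "ndvi")
  rownames(X) <- paste(records$region_id, records$epoch, sep = "@")
  attr(X, "region_id") <- records$region_id
  attr(X, "epoch") <- records$epoch
  X
}

#' Cosangle distance between factor vectors
#'
#' One minus the cosine of the angle between two vectors (default), in
#' `[0, 2]`; or the chordal square-root variant
#' `sqrt(2 * (1 - cos))` used by some implementations of ordered
#' partitioning clustering.
#'
#' @param x,y non-zero numeric vectors.
#' @param variant `"oneminus"` (default) or `"sqrt"`.
#' @return the distance.
#' @export
cosangle <- function(x, y, variant = c("oneminus", "sqrt")) {
  variant <- match.arg(variant)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("cosangle is undefined for zero vectors")
  cs <- sum(x * y) / (nx * ny)
  cs <- min(max(cs, -1), 1)
  if (variant == "oneminus") 1 - cs else sqrt(2 * (1 - cs))
}

# full pairwise cosangle dissimilarity for rows of X
cosangle_dist <- function(X, variant = c("oneminus", "sqrt")) {
  variant <- match.arg(variant)
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0))
    stop("cosangle is undefined for zero rows; drop them first")
  cs <- tcrossprod(X / nrm)
  cs <- pmin(pmax(cs, -1), 1)
  D <- if (variant == "oneminus") 1 - cs else sqrt(pmax(2 * (1 - cs), 0))
  stats::as.dist(D)
}

# drop zero-norm rows (cosangle undefined) with a warning
drop_zero_rows <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) {
    warning(sum(nrm == 0),
            " row(s) with zero feature vector dropped (cosangle undefined)")
    keep <- nrm > 0
    att <- list(region_id = attr(X, "region_id")[keep],
                epoch = attr(X, "epoch")[keep])
    X <- X[keep, , drop = FALSE]
    attr(X, "region_id") <- att$region_id
    attr(X, "epoch") <- att$epoch
  }
  X
}

#' One-level k-medoids clustering of factor profiles
#'
#' Partitions the pooled (region, epoch) rows into `k` clusters by k-medoids
#' (PAM build + swap) under the cosangle metric — one flat level of
#' maximally homogeneous clusters. Cluster numbers are made reproducible by
#' relabelling clusters in order of decreasing mean normalized canopy
#' height, so cluster 1 is always the tallest-profile cluster.
#'
#' @param X feature matrix from [normalize_features()] (rows >= k).
#' @param k number of clusters (default 8).
#' @param seed integer seed (the PAM fit itself is deterministic; the seed
#'   fixes any downstream randomness for reproducibility).
#' @param variant cosangle variant, see [cosangle()].
#' @return object of class `cluster_model`: `k`, `labels` (per row),
#'   `medoids` (row indices), `medoid_vectors`, `metric`.
#' @export
cluster_cells <- function(X, k = 8, seed = 1L, variant = "oneminus") {
  X <- drop_zero_rows(X)
  if (nrow(X) < k)
    stop("insufficient-data error: ", nrow(X), " rows for k = ", k)
  set.seed(seed)
  Dfull <- as.matrix(cosangle_dist(X, variant))
  if (k == 1L) {
    labels <- rep(1L, nrow(X))
  } else {
    pm <- cluster::pam(stats::as.dist(Dfull), k = k, diss = TRUE)
    labels <- as.integer(pm$clustering)
  }
  # stable ordering: relabel by mean normalized ACH, descending
  ach_mean <- tapply(X[, "ach"], labels, mean)
  ord <- order(-ach_mean)
  relabel <- integer(k)
  relabel[as.integer(names(ach_mean))[ord]] <- seq_len(k)
  labels <- relabel[labels]
  # medoid of each (relabelled) cluster
  med_by_label <- integer(k)
  for (cl in seq_len(k)) {
    rows <- which(labels == cl)
    Dm <- Dfull[rows, rows, drop = FALSE]
    med_by_label[cl] <- rows[which.min(rowSums(Dm))]
  }
  structure(list(
    k = as.integer(k), labels = labels, medoids = med_by_label,
    medoid_vectors = X[med_by_label, , drop = FALSE],
    metric = variant,
    region_id = attr(X, "region_id"), epoch = attr(X, "epoch")
  ), class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: k = %d (%s metric), sizes %s\n", x$k, x$metric,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

#' Bootstrap fuzzy cluster memberships
#'
#' Non-parametric bootstrap of the clustering: each replicate resamples the
#' rows with replacement, refits the k-medoids model on the resample,
#' matches the replicate's clusters to the original ones by greedy
#' nearest-medoid pairing (ties to the lowest cluster index), and assigns
#' every original row to its nearest matched medoid. The membership of a row
#' in a cluster is the fraction of replicates assigning it there, so each
#' row of the result sums to 1.
#'
#' @param X feature matrix (as passed to [cluster_cells()]).
#' @param model a fitted `cluster_model`.
#' @param reps number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @return n x k membership matrix, rows summing to 1.
#' @export
bootstrap_membership <- function(X, model, reps = 100, seed = 1L) {
  if (reps < 1) stop("domain error: reps must be >= 1")
  X <- drop_zero_rows(X)
  n <- nrow(X); k <- model$k
  set.seed(seed)
  counts <- matrix(0L, n, k)
  for (b in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    Xb <- X[idx, , drop = FALSE]
    if (length(unique(idx)) < k) next  # degenerate resample, skip
    fitb <- cluster::pam(cosangle_dist(Xb, model$metric), k = k, diss = TRUE)
    med_rows <- idx[as.integer(fitb$id.med)]
    # greedy matching of replicate medoids to original medoids
    Dm <- matrix(0, k, k)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      Dm[i, j] <- cosangle(model$medoid_vectors[i, ], X[med_rows[j], ],
                           variant = model$metric)
    }
    map <- integer(k)  # replicate cluster j -> original cluster map[j]
    free_i <- rep(TRUE, k); free_j <- rep(TRUE, k)
    for (step in seq_len(k)) {
      Dv <- Dm
      Dv[!free_i, ] <- Inf; Dv[, !free_j] <- Inf
      w <- which(Dv == min(Dv), arr.ind = TRUE)[1, ]  # lowest index on ties
      map[w["col"]] <- w["row"]
      free_i[w["row"]] <- FALSE; free_j[w["col"]] <- FALSE
    }
    # assign each original row to nearest replicate medoid
    for (r in seq_len(n)) {
      dd <- vapply(seq_len(k), function(j)
        cosangle(X[r, ], X[med_rows[j], ], variant = model$metric),
        numeric(1))
      counts[r, map[which.min(dd)]] <- counts[r, map[which.min(dd)]] + 1L
    }
  }
  M <- counts / rowSums(counts)
  rownames(M) <- rownames(X)
  M
}

#' Cross-epoch cluster exchange matrix
#'
#' Tabulates, over the regions present in both epochs, the flow of regions
#' from their epoch-A cluster (rows) to their epoch-B cluster (columns). Row
#' sums equal epoch-A cluster sizes, column sums epoch-B sizes, and the
#' grand total the number of common regions; the diagonal counts stable
#' membership.
#'
#' @param labels_a,labels_b integer cluster labels named by region id.
#' @param k number of clusters.
#' @return k x k integer matrix of class `exchange_matrix`.
#' @export
exchange_matrix <- function(labels_a, labels_b, k) {
  if (is.null(names(labels_a)) || is.null(names(labels_b)))
    stop("validation error: labels must be named by region id")
  if (!setequal(names(labels_a), names(labels_b)))
    stop("validation error: mismatched region sets between epochs")
  ids <- names(labels_a)
  tab <- table(factor(labels_a[ids], levels = seq_len(k)),
               factor(labels_b[ids], levels = seq_len(k)))
  M <- matrix(as.integer(tab), k, k,
              dimnames = list(epoch_a = seq_len(k), epoch_b = seq_len(k)))
  class(M) <- c("exchange_matrix", class(M))
  M
}

#' Split pooled labels by epoch
#'
#' Convenience: takes a fitted `cluster_model` over pooled (region, epoch)
#' rows and returns the per-epoch label vectors named by region id.
#'
#' @param model a `cluster_model` fitted on [normalize_features()] output.
#' @return named list of named integer vectors, one per epoch.
#' @export
labels_by_epoch <- function(model) {
  eps <- sort(unique(model$epoch))
  out <- lapply(eps, function(e) {
    sel <- model$epoch == e
    stats::setNames(model$labels[sel], model$region_id[sel])
  })
  names(out) <- eps
  out
}

#' Exchange network edge list
#'
#' Off-diagonal flows of an [exchange_matrix()] as a directed edge list.
#'
#' @param M an `exchange_matrix`.
#' @return data.frame `source`, `target`, `count` (positive flows only).
#' @export
exchange_edges <- function(M) {
  k <- nrow(M)
  idx <- which(M > 0 & row(M) != col(M), arr.ind = TRUE)
  data.frame(source = idx[, 1], target = idx[, 2],
             count = M[idx])
}

#' Per-cluster factor profiles
#'
#' Mean raw and normalized factors (and MCPI when present) per cluster, with
#' per-epoch cluster sizes and the growth percentage of each cluster between
#' the first and last epoch.
#'
#' @param model a `cluster_model`.
#' @param X the feature matrix the model was fitted on.
#' @param records the records used to build `X` (aligned rows; must contain
#'   `amw_m`, `ach_m`, `ndvi`, optionally `mcpi`).
#' @return data.frame, one row per cluster.
#' @export
cluster_profiles <- function(model, X, records) {
  X <- drop_zero_rows(X)
  stopifnot(nrow(X) == length(model$labels))
  key_x <- paste(attr(X, "region_id"), attr(X, "epoch"), sep = "@")
  key_r <- paste(records$region_id, records$epoch, sep = "@")
  records <- records[match(key_x, key_r), , drop = FALSE]
  lab <- model$labels
  eps <- sort(unique(model$epoch))
  out <- lapply(seq_len(model$k), function(cl) {
    sel <- lab == cl
    sizes <- vapply(eps, function(e) sum(sel & model$epoch == e), integer(1))
    growth <- if (length(eps) >= 2 && sizes[1] > 0)
      (sizes[length(sizes)] - sizes[1]) / sizes[1] * 100 else NA_real_
    data.frame(
      cluster = cl, size = sum(sel),
      amw_m = mean(records$amw_m[sel]), ach_m = mean(records$ach_m[sel]),
      ndvi = mean(records$ndvi[sel]),
      amw_norm = mean(X[sel, "amw"]), ach_norm = mean(X[sel, "ach"]),
      ndvi_norm = mean(X[sel, "ndvi"]),
      mcpi = if ("mcpi" %in% names(records)) mean(records$mcpi[sel])
             else NA_real_,
      size_first = sizes[1], size_last = sizes[length(sizes)],
      growth_pct = growth)
  })
  do.call(rbind, out)
}
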