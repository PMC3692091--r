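# Trajectory analysis: fluctuation profile, K-means clustering with medoid
# representatives, density ranking.

#' Compute the per-residue mean-square-fluctuation profile
#'
#' All frames are first superimposed onto their iteratively computed mean
#' structure by maximum-likelihood superposition ([ml_superpose()]), whose
#' variance-based downweighting keeps mobile residues from dragging the fit
#' and so from having part of their motion absorbed into the global
#' rigid-body transform; the profile is then
#' msf_i = (1/M) * sum_j ||x_ij - mean_i||^2, the mean squared deviation of
#' residue i from its trajectory-average position, in square Angstrom.
#'
#' @param traj A `cabs_trajectory`, or a list of n x 3 Calpha frames.
#' @return An object of class `fluct_profile`: data frame with columns
#'   `residue` and `msf`.
#' @export
compute_msf <- function(traj) {
  frames <- if (inherits(traj, "cabs_trajectory")) traj$frames else traj
  stopifnot(is.list(frames), length(frames) >= 1)
  n <- nrow(frames[[1]])
  if (length(frames) < 2) {
    warning("single-frame trajectory: fluctuation profile is all zero")
    return(new_fluct_profile(rep(0, n)))
  }
  aligned <- ml_superpose(frames)$aligned
  mean_s <- Reduce(`+`, aligned) / length(aligned)
  msf <- rowMeans(vapply(aligned, function(a) rowSums((a - mean_s)^2),
                         numeric(n)))
  new_fluct_profile(msf)
}

new_fluct_profile <- function(msf) {
  structure(data.frame(residue = seq_along(msf), msf = msf),
            class = c("fluct_profile", "data.frame"))
}

#' @export
plot.fluct_profile <- function(x, ...) {
  plot(x$residue, x$msf, type = "l", xlab = "residue",
       ylab = expression(MSF ~ (ring(A)^2)),
       main = "residue fluctuation profile", ...)
  invisible(x)
}

#' Cluster trajectory frames by K-means
#'
#' Frames are superimposed onto their iteratively computed mean structure and
#' clustered by classical (Lloyd) K-means on the flattened Calpha
#' coordinates, initialized with k-means++ under the given seed. Each
#' cluster's representative is its medoid: the member frame whose average
#' dissimilarity (pairwise Calpha RMSD over the common superposition) to all
#' co-members is minimal. Cluster density is size / (1 + mean
#' member-to-medoid RMSD), which rewards populous, structurally tight
#' clusters.
#'
#' @param traj A `cabs_trajectory` or list of frames.
#' @param k Number of clusters (at most the number of frames).
#' @param seed Integer seed for the k-means++ initialization.
#' @return An object of class `cluster_result`: `assignment` (frame ->
#'   cluster id), `medoid_frame_ids`, `density`, `rank_order` (cluster ids
#'   sorted by decreasing density, ties broken by lower id), `sizes`,
#'   `mean_rmsd_to_medoid`, `k`.
#' @export
cluster_frames <- function(traj, k = 10, seed = 1) {
  frames <- if (inherits(traj, "cabs_trajectory")) traj$frames else traj
  M <- length(frames)
  if (k > M) stop("k must not exceed the number of frames", call. = FALSE)
  n <- nrow(frames[[1]])
  X <- frames_matrix(superpose_to_mean(frames))

  set.seed(seed)
  assignment <- if (k == 1) rep(1L, M) else lloyd_assign(X, k)

  medoid <- integer(k)
  dens <- numeric(k)
  sizes <- integer(k)
  mean_rmsd <- numeric(k)
  for (c in seq_len(k)) {
    members <- which(assignment == c)
    sizes[c] <- length(members)
    D <- as.matrix(stats::dist(X[members, , drop = FALSE])) / sqrt(n)
    avg <- rowMeans(D)  # includes self-distance 0; argmin is unaffected
    medoid_local <- which.min(avg)  # which.min takes the first on ties
    medoid[c] <- members[medoid_local]
    mean_rmsd[c] <- mean(D[, medoid_local])
    dens[c] <- sizes[c] / (1 + mean_rmsd[c])
  }
  rank_order <- order(-dens, seq_len(k))

  structure(list(assignment = assignment, medoid_frame_ids = medoid,
                 density = dens, rank_order = rank_order, sizes = sizes,
                 mean_rmsd_to_medoid = mean_rmsd, k = k),
            class = "cluster_result")
}

# Lloyd K-means with k-means++ initialization; an empty-cluster failure is
# retried with a fresh k-means++ draw from the running RNG stream
lloyd_assign <- function(X, k, max_tries = 5) {
  for (try in seq_len(max_tries)) {
    centers <- X[kmeanspp_init(X, k), , drop = FALSE]
    fit <- tryCatch(
      stats::kmeans(X, centers = centers, iter.max = 100,
                    algorithm = "Lloyd"),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) return(fit$cluster)
  }
  stop("K-means failed to produce k non-empty clusters", call. = FALSE)
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center
kmeanspp_init <- function(X, k) {
  M <- nrow(X)
  ids <- integer(k)
  ids[1] <- sample.int(M, 1)
  d2 <- colSums((t(X) - X[ids[1], ])^2)
  for (c in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      ids[c + 1] <- sample.int(M, 1)
    } else {
      ids[c + 1] <- sample.int(M, 1, prob = d2)
    }
    d2 <- pmin(d2, colSums((t(X) - X[ids[c + 1], ])^2))
  }
  ids
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("K-means clustering: k = %d\n", x$k))
  for (r in seq_len(x$k)) {
    c <- x$rank_order[r]
    cat(sprintf("  rank %d: cluster %d, size %d, density %.3f, medoid frame %d\n",
                r, c, x$sizes[c], x$density[c], x$medoid_frame_ids[c]))
  }
  invisible(x)
}

#' Rank clusters by density and extract representative models
#'
#' Orders clusters from the most dense to the least dense (ties broken by
#' lower cluster id) and emits the medoid Calpha frame of each, so that
#' Model n represents Cluster n in the ranked numbering.
#'
#' @param cr A `cluster_result`.
#' @param traj The `cabs_trajectory` (or frame list) that was clustered.
#' @return An object of class `model_ensemble`: list `models`, each with
#'   `rank`, `cluster` (original id), `frame_id`, `size`, `density`, `ca`;
#'   plus `sequence` when available.
#' @export
rank_and_extract <- function(cr, traj) {
  stopifnot(inherits(cr, "cluster_result"))
  frames <- if (inherits(traj, "cabs_trajectory")) traj$frames else traj
  models <- lapply(seq_len(cr$k), function(r) {
    c <- cr$rank_order[r]
    fid <- cr$medoid_frame_ids[c]
    list(rank = r, cluster = c, frame_id = fid, size = cr$sizes[c],
         density = cr$density[c], ca = frames[[fid]])
  })
  structure(list(models = models,
                 sequence = if (inherits(traj, "cabs_trajectory"))
                   traj$sequence else NULL),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf("model ensemble: %d ranked representatives\n",
              length(x$models)))
  for (m in x$models)
    cat(sprintf("  Model %d (Cluster %d): frame %d, size %d, density %.3f\n",
                m$rank, m$cluster, m$frame_id, m$size, m$density))
  invisible(x)
}

#' Write the cluster report as plain text
#'
#' Per ranked cluster: rank, original cluster id, size, density, medoid frame
#' index.
#'
#' @param cr A `cluster_result`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cluster_report <- function(cr, path) {
  lines <- c("rank cluster size density medoid_frame")
  for (r in seq_len(cr$k)) {
    c <- cr$rank_order[r]
    lines <- c(lines, sprintf("%d %d %d %.4f %d", r, c, cr$sizes[c],
                              cr$density[c], cr$medoid_frame_ids[c]))
  }
  writeLines(lines, path)
  invisible(path)
}
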