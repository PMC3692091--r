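# Rigid-body superposition: closed-form weighted least squares (Kabsch) and
# iterative maximum-likelihood multiple superposition with variance-based
# downweighting of flexible regions.

#' Optimal weighted least-squares superposition of two point sets
#'
#' Computes the proper rotation and translation minimizing the (weighted) sum
#' of squared distances from the transformed mobile set to the target;
#' reflections are excluded by the determinant correction of the SVD
#' solution. The aligned mobile coordinates are
#' `(mobile - mobile_centroid) %*% rotation + target_centroid + translation0`,
#' i.e. `sweep(mobile %*% rotation, 2, translation, "+")`.
#'
#' @param mobile,target Coordinate matrices (n x 3), equal n >= 3.
#' @param weights Optional non-negative per-point weights, not all zero.
#' @return List with `rotation` (3 x 3, right-multiplied), `translation`
#'   (length 3), `rmsd` (weighted root-mean-square deviation after
#'   superposition) and `aligned` (transformed mobile coordinates).
#' @export
kabsch_superpose <- function(mobile, target, weights = NULL) {
  stopifnot(is.matrix(mobile), is.matrix(target),
            nrow(mobile) == nrow(target), ncol(mobile) == 3)
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs at least 3 points", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative and not all zero", call. = FALSE)
  w <- weights / sum(weights)

  cm <- colSums(mobile * w)
  ct <- colSums(target * w)
  A <- sweep(mobile, 2, cm)
  B <- sweep(target, 2, ct)

  # rank check: fewer than 3 effective non-collinear points leaves the
  # rotation underdetermined
  sv_a <- svd(A * sqrt(w))$d
  if (sv_a[2] < 1e-8)
    stop("rank-deficient point set: superposition is not unique", call. = FALSE)

  H <- t(A * w) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)

  aligned <- sweep(A %*% R, 2, ct, "+")
  rmsd <- sqrt(sum(w * rowSums((aligned - target)^2)))
  list(rotation = R, translation = ct - as.vector(cm %*% R),
       rmsd = rmsd, aligned = aligned)
}

#' Iterative maximum-likelihood multiple superposition
#'
#' Simultaneously superimposes two or more equal-length models by iterating:
#' (a) align each model to the current mean structure by weighted
#' least squares with per-residue weights 1 / (sigma_i^2 + eps); (b) update
#' the mean structure; (c) re-estimate the per-residue isotropic variances
#' sigma_i^2 from the residuals. Variable regions therefore carry little
#' weight in the fit, which is the behaviour that distinguishes
#' maximum-likelihood superposition from plain least squares. Iteration stops
#' when the mean structure moves less than `tol` (RMS) or after `max_iter`
#' iterations.
#'
#' The covariance model is per-residue isotropic (a diagonal approximation of
#' the full atom-covariance treatment); `eps` (1e-4 square Angstrom) floors
#' the variances so invariant residues cannot receive infinite weight.
#'
#' @param models List of n x 3 coordinate matrices (>= 2, equal n).
#' @param max_iter Maximum iterations.
#' @param tol Convergence threshold on the RMS mean-structure shift,
#'   Angstrom.
#' @param eps Variance floor, square Angstrom.
#' @param weighted Use variance weights (`TRUE`, the default); `FALSE` gives
#'   plain iterative-mean least-squares superposition.
#' @return An object of class `superposition_result`: `rotations`,
#'   `translations`, `mean_structure`, `per_residue_variance` (sigma_i^2 per
#'   coordinate, square Angstrom), `rmsd_to_mean` (per model, unweighted),
#'   `iterations`, `converged`, `objective` (data frame with the weighted
#'   objective before and after each iteration's realignment, under that
#'   iteration's weights) and `aligned` (list of superimposed models).
#' @export
ml_superpose <- function(models, max_iter = 50, tol = 1e-6, eps = 1e-4,
                         weighted = TRUE) {
  stopifnot(is.list(models), length(models) >= 2)
  n <- nrow(models[[1]])
  for (m in models) stopifnot(is.matrix(m), nrow(m) == n, ncol(m) == 3)
  M <- length(models)

  # initial alignment to the first model
  aligned <- lapply(models, function(m) kabsch_superpose(m, models[[1]])$aligned)
  mean_s <- Reduce(`+`, aligned) / M
  variance <- residue_variance(aligned, mean_s)

  converged <- FALSE
  iter <- 0
  obj_before <- numeric(0)
  obj_after <- numeric(0)
  fits <- NULL
  while (iter < max_iter) {
    iter <- iter + 1
    w <- if (weighted) 1 / (pmax(variance, 0) + eps) else rep(1, n)
    obj_before[iter] <- weighted_objective(aligned, mean_s, w)
    fits <- lapply(aligned, kabsch_superpose, target = mean_s, weights = w)
    aligned <- lapply(fits, `[[`, "aligned")
    new_mean <- weighted_mean_structure(aligned, w)
    obj_after[iter] <- weighted_objective(aligned, new_mean, w)
    shift <- sqrt(mean((new_mean - mean_s)^2))
    mean_s <- new_mean
    variance <- residue_variance(aligned, mean_s)
    if (shift < tol) { converged <- TRUE; break }
  }

  # compose total transforms model -> aligned
  rotations <- vector("list", M)
  translations <- vector("list", M)
  for (m in seq_len(M)) {
    fit <- kabsch_superpose(models[[m]], aligned[[m]])
    rotations[[m]] <- fit$rotation
    translations[[m]] <- fit$translation
  }
  rmsd_to_mean <- vapply(aligned, function(a)
    sqrt(mean(rowSums((a - mean_s)^2))), numeric(1))

  structure(list(rotations = rotations, translations = translations,
                 mean_structure = mean_s,
                 per_residue_variance = pmax(variance, 0),
                 rmsd_to_mean = rmsd_to_mean,
                 iterations = iter, converged = converged,
                 objective = data.frame(iteration = seq_len(iter),
                                        before = obj_before,
                                        after = obj_after),
                 aligned = aligned),
            class = "superposition_result")
}

# per-residue isotropic variance (per coordinate): mean squared residual / 3
residue_variance <- function(aligned, mean_s) {
  M <- length(aligned)
  acc <- rowSums(Reduce(`+`, lapply(aligned, function(a) (a - mean_s)^2)))
  acc / (3 * M)
}

weighted_objective <- function(aligned, mean_s, w) {
  sum(vapply(aligned, function(a) sum(w * rowSums((a - mean_s)^2)),
             numeric(1)))
}

# the mean minimizing the weighted objective is the plain per-residue mean
# (weights are per residue, shared across models)
weighted_mean_structure <- function(aligned, w) {
  Reduce(`+`, aligned) / length(aligned)
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("ML superposition of %d models: %d iterations, %s\n",
              length(x$rotations), x$iterations,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  mean per-residue variance %.4f A^2, rmsd to mean %.3f - %.3f A\n",
              mean(x$per_residue_variance), min(x$rmsd_to_mean),
              max(x$rmsd_to_mean)))
  invisible(x)
}

# superimpose a list of frames onto their iteratively computed (unweighted)
# mean structure; used by the fluctuation and clustering stages
superpose_to_mean <- function(frames, max_iter = 50, tol = 1e-6) {
  if (length(frames) == 1) return(frames)
  ml_superpose(frames, max_iter = max_iter, tol = tol,
               weighted = FALSE)$aligned
}
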