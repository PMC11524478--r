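#' Extract scale-invariant interest points from a panel
#'
#' Detects difference-of-Gaussians interest points on the BT.601 grayscale
#' version of the panel and computes 128-dimensional gradient-histogram
#' descriptors. The detector is deterministic: the same raster always yields
#' the same interest point set. Zero keypoints (e.g. on a uniform panel) is a
#' valid outcome.
#'
#' @param panel a \linkS4class{Panel}, or an h x w x 3 raster array.
#' @param upscale logical; start the pyramid from a 2x upsampled image
#'   (default TRUE, recovers more structure on small panels).
#' @return a list with class "InterestPointSet": `coordinates` (n x 2 matrix
#'   of 0-based x, y pixel positions), `descriptions` (n x 128 matrix),
#'   `scale` and `angle` vectors.
#' @export
extractKeypoints <- function(panel, upscale = TRUE) {
  raster <- if (is(panel, "Panel")) panel@raster else panel
  gray <- toGray(asRGB(raster))
  res <- .sift_detect(gray, upscale = upscale)
  out <- list(coordinates = res$points[, c("x", "y"), drop = FALSE],
              descriptions = res$descriptors,
              scale = res$points[, "size"],
              angle = res$points[, "angle"])
  class(out) <- "InterestPointSet"
  out
}

#' @export
print.InterestPointSet <- function(x, ...) {
  cat(sprintf("InterestPointSet: %d keypoints\n", nrow(x$coordinates)))
  invisible(x)
}

# direct linear transform homography (normalized), src/dst are n x 2
estimateHomographyDLT <- function(src, dst) {
  n <- nrow(src)
  if (n < 4) return(NULL)
  normalize <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- if (mean(d) > 1e-12) sqrt(2) / mean(d) else 1
    T <- matrix(c(s, 0, -s * ctr[1], 0, s, -s * ctr[2], 0, 0, 1), 3, 3, byrow = TRUE)
    list(p = cbind(s * (p[, 1] - ctr[1]), s * (p[, 2] - ctr[2])), T = T)
  }
  n1 <- normalize(src); n2 <- normalize(dst)
  x <- n1$p[, 1]; y <- n1$p[, 2]; u <- n2$p[, 1]; v <- n2$p[, 2]
  A <- matrix(0, 2 * n, 9)
  A[seq(1, 2 * n, 2), ] <- cbind(x, y, 1, 0, 0, 0, -u * x, -u * y, -u)
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, x, y, 1, -v * x, -v * y, -v)
  h <- tryCatch(svd(A, nu = 0, nv = 9)$v[, 9], error = function(e) NULL)
  if (is.null(h)) return(NULL)
  Hn <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(n2$T) %*% Hn %*% n1$T
  if (abs(H[3, 3]) < 1e-12) return(NULL)
  H / H[3, 3]
}

# apply homography to n x 2 points
applyHomography <- function(H, p) {
  q <- cbind(p, 1) %*% t(H)
  cbind(q[, 1] / q[, 3], q[, 2] / q[, 3])
}

# robust fit + least-squares refit; returns NULL or list(H, inliers)
robustHomography <- function(src, dst, tol, maxIter, seed) {
  n <- nrow(src)
  if (n < 4) return(NULL)
  fit <- .ransac_homography(src[, 1], src[, 2], dst[, 1], dst[, 2],
                            tol = tol, max_iter = maxIter, seed = seed)
  if (!fit$found || length(fit$inliers) < 4) return(NULL)
  inl <- fit$inliers
  H <- fit$H
  # two refit passes: least squares on the consensus set, re-select inliers
  for (i in 1:2) {
    H2 <- estimateHomographyDLT(src[inl, , drop = FALSE], dst[inl, , drop = FALSE])
    if (is.null(H2)) break
    err <- rowSums((applyHomography(H2, src) - dst)^2)
    inl2 <- which(err < tol^2)
    if (length(inl2) < 4) break
    H <- H2
    inl <- inl2
  }
  list(H = H, inliers = inl)
}

# guided matching: with the homography known, re-match keypoints under the
# geometric constraint (projection within the reprojection tolerance) using
# an absolute descriptor-distance gate. Recovers correct correspondences --
# typically near panel borders -- whose ratio-test score was ambiguous, so
# the matched region reflects the full shared content.
guidedMatches <- function(kpP, kpR, H, tol, maxDescDist = 1.2) {
  proj <- applyHomography(H, kpP$coordinates)
  src <- NULL; dst <- NULL
  for (i in seq_len(nrow(proj))) {
    d2 <- (kpR$coordinates[, 1] - proj[i, 1])^2 +
      (kpR$coordinates[, 2] - proj[i, 2])^2
    cand <- which(d2 < tol^2)
    if (length(cand) == 0) next
    dd <- sqrt(colSums((t(kpR$descriptions[cand, , drop = FALSE]) -
                          kpP$descriptions[i, ])^2))
    j <- cand[which.min(dd)]
    if (min(dd) < maxDescDist) {
      src <- rbind(src, kpP$coordinates[i, ])
      dst <- rbind(dst, kpR$coordinates[j, ])
    }
  }
  list(src = src, dst = dst)
}

# brute-force descriptor matching under Lowe's ratio test; squared L2
# distances via BLAS (||a||^2 + ||b||^2 - 2 a.b), then a ratio-test scan
matchDescriptors <- function(d1, d2, ratio) {
  if (nrow(d1) == 0 || nrow(d2) < 2)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("idx1", "idx2"))))
  dist2 <- outer(rowSums(d1^2), rowSums(d2^2), "+") - 2 * (d1 %*% t(d2))
  .ratio_best(dist2, ratio)
}

# single matching attempt between two keypoint sets; NULL when it fails
matchAttempt <- function(kpP, kpR, cfg, seed) {
  if (nrow(kpP$coordinates) < 4 || nrow(kpR$coordinates) < 4) return(NULL)
  m <- matchDescriptors(kpP$descriptions, kpR$descriptions, ratio = cfg@ratio)
  if (nrow(m) < max(4L, cfg@minInliers)) return(NULL)
  src <- kpP$coordinates[m[, 1], , drop = FALSE]
  dst <- kpR$coordinates[m[, 2], , drop = FALSE]
  fit <- robustHomography(src, dst, tol = cfg@reprojTol,
                          maxIter = cfg@maxIter, seed = seed)
  if (is.null(fit) || length(fit$inliers) < cfg@minInliers) return(NULL)
  out <- list(H = fit$H,
              src = src[fit$inliers, , drop = FALSE],
              dst = dst[fit$inliers, , drop = FALSE])
  g <- guidedMatches(kpP, kpR, fit$H, cfg@reprojTol)
  if (!is.null(g$src) && nrow(g$src) >= nrow(out$src)) {
    out$src <- g$src
    out$dst <- g$dst
  }
  out
}

#' Verify content consistency between two panels
#'
#' Matches interest-point descriptors with a brute-force nearest-neighbour
#' search under Lowe's ratio test, then fits a homography with a robust
#' (RANSAC-family, truncated-loss) estimator. If the unflipped attempt yields
#' fewer than `minInliers` consistent matches, the attempt is repeated with
#' the mirrored panel P' (scale-invariant descriptors are not robust to
#' mirroring). A pair is consistent when either attempt retains at least
#' `minInliers` matches; degenerate geometry is reported as inconsistent,
#' never as an error.
#'
#' @param P,R \linkS4class{Panel} objects (P != R).
#' @param cfg a \linkS4class{RetrievalConfig}.
#' @param kpP,kpR optional precomputed interest point sets (see
#'   [extractKeypoints()]); pass them when matching many pairs.
#' @param kpPFlip optional precomputed interest points of the mirrored P.
#' @return a \linkS4class{MatchResult}. Inlier coordinates on the P side are
#'   reported in P's unflipped frame and the homography maps that frame to R,
#'   also when `mirrored` is TRUE.
#' @export
matchAndVerify <- function(P, R, cfg = retrievalConfig(), kpP = NULL,
                           kpR = NULL, kpPFlip = NULL) {
  stopifnot(is(P, "Panel"), is(R, "Panel"))
  if (identical(P@panelId, R@panelId))
    stop("matchAndVerify requires two distinct panels")
  if (is.null(kpP)) kpP <- extractKeypoints(P)
  if (is.null(kpR)) kpR <- extractKeypoints(R)
  seed <- (as.double(cfg@seed) + as.double(stringHash(paste(P@panelId, R@panelId)))) %% 2^31

  att <- matchAttempt(kpP, kpR, cfg, seed)
  mirrored <- FALSE
  if (is.null(att)) {
    if (is.null(kpPFlip))
      kpPFlip <- extractKeypoints(flipRaster(P@raster, cfg@flipAxis))
    att <- matchAttempt(kpPFlip, kpR, cfg, seed + 1)
    if (!is.null(att)) {
      mirrored <- TRUE
      w <- panelWidth(P); h <- panelHeight(P)
      # map flipped-frame coordinates and homography back to P's frame
      Fm <- if (cfg@flipAxis == "horizontal")
        matrix(c(-1, 0, w - 1, 0, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE)
      else
        matrix(c(1, 0, 0, 0, -1, h - 1, 0, 0, 1), 3, 3, byrow = TRUE)
      att$src <- applyHomography(Fm, att$src)  # involution: flip back
      att$H <- att$H %*% Fm
      att$H <- att$H / att$H[3, 3]
    }
  }
  if (is.null(att)) {
    return(new("MatchResult", panelP = P@panelId, panelR = R@panelId,
               inlierP = matrix(numeric(0), 0, 2),
               inlierR = matrix(numeric(0), 0, 2),
               homography = diag(3), mirrored = FALSE, consistent = FALSE))
  }
  new("MatchResult", panelP = P@panelId, panelR = R@panelId,
      inlierP = unname(att$src), inlierR = unname(att$dst),
      homography = unname(att$H), mirrored = mirrored, consistent = TRUE)
}

#' Construct a MatchResult from known correspondences
#'
#' Useful for scoring constructed examples where the matched points are known
#' by construction rather than detected.
#'
#' @param panelP,panelR panel ids.
#' @param inlierP,inlierR n x 2 coordinate matrices (P frame / R frame).
#' @param homography optional 3 x 3 matrix (default identity).
#' @param mirrored logical flag.
#' @return a consistent \linkS4class{MatchResult}.
#' @export
matchResult <- function(panelP, panelR, inlierP, inlierR,
                        homography = diag(3), mirrored = FALSE) {
  stopifnot(nrow(inlierP) == nrow(inlierR))
  new("MatchResult", panelP = panelP, panelR = panelR,
      inlierP = as.matrix(inlierP), inlierR = as.matrix(inlierR),
      homography = homography, mirrored = mirrored, consistent = TRUE)
}

# area of the convex hull of matched pixel positions, clipped to the panel.
# Matched interest points mark pixels: each point (a pixel center) is dilated
# to its unit pixel square before the hull, so corner-to-corner matches cover
# the panel exactly. The polygon area uses the shoelace formula.
hullAreaPixels <- function(points, width, height) {
  if (nrow(points) == 0) return(0)
  ex <- c(points[, 1] - 0.5, points[, 1] + 0.5,
          points[, 1] - 0.5, points[, 1] + 0.5)
  ey <- c(points[, 2] - 0.5, points[, 2] - 0.5,
          points[, 2] + 0.5, points[, 2] + 0.5)
  ex <- pmin(pmax(ex, -0.5), width - 0.5)
  ey <- pmin(pmax(ey, -0.5), height - 0.5)
  idx <- grDevices::chull(ex, ey)
  if (length(idx) < 3) return(0)
  shoelaceArea(ex[idx], ey[idx])
}

shoelaceArea <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Content-sharing score of a verified panel pair
#'
#' Implements the directional score: the area of the convex hull of the
#' matched interest points on one side, divided by that panel's area. A panel
#' that is entirely covered by the matched region scores 1.0 regardless of
#' the other panel's size, so a crop covering 50% of its source scores
#' (1.0, 0.5) in the two directions. Fewer than 3 non-collinear inliers on a
#' side yield a 0 score for that side.
#'
#' @param match a consistent \linkS4class{MatchResult} (an inconsistent match
#'   is a contract violation and raises an error).
#' @param P,R the matched \linkS4class{Panel} objects.
#' @return named numeric vector `c(score_P_given_R =, score_R_given_P =)`,
#'   both in [0, 1].
#' @export
contentSharingScore <- function(match, P, R) {
  stopifnot(is(match, "MatchResult"))
  if (!match@consistent)
    stop("content-sharing score is defined only for consistent matches")
  sp <- hullAreaPixels(match@inlierP, panelWidth(P), panelHeight(P)) /
    (panelWidth(P) * panelHeight(P))
  sr <- hullAreaPixels(match@inlierR, panelWidth(R), panelHeight(R)) /
    (panelWidth(R) * panelHeight(R))
  c(score_P_given_R = min(max(sp, 0), 1), score_R_given_P = min(max(sr, 0), 1))
}
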