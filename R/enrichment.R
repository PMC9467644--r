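# Chloroplast co-localization enrichment.
#
# E compares mitochondrial density in chloroplast-adjacent area with the
# density in the rest of the cell, per frame:
#
#   E = (Nc / Ac) / ((N - Nc) / (A - Ac))
#
# where N is the number of mitochondria present in the frame, Nc those
# within distance d of the centre of their nearest chloroplast, A the cell
# area and Ac the chloroplast-adjacent area estimate (pi * d^2 per
# chloroplast present). Under a random arrangement of organelles the two
# densities agree and E ~ 1.

#' Chloroplast co-localization enrichment E
#'
#' Computes the enrichment ratio per frame and its mean over frames with a
#' defined value. `d` defaults to 3 µm, twice the typical 1.5 µm
#' chloroplast radius, and adjacency is measured to the centre of the
#' nearest chloroplast, so each mitochondrion is counted at most once even
#' where adjacency zones overlap. `Ac` sums `pi * d^2` over the
#' chloroplasts present in the frame without subtracting zone overlaps;
#' set `overlapCorrect = TRUE` to estimate the union area on a grid
#' instead.
#'
#' Frames where no chloroplast is present, where `Ac >= A`, or where every
#' mitochondrion is adjacent (`N - Nc = 0`, infinite ratio) have no defined
#' E; they are excluded from the mean with a warning when any occur.
#'
#' @param mitoTs mitochondrial [TrajectorySet-class].
#' @param chloroTs chloroplast [TrajectorySet-class] sharing the frame
#'   structure; positions are the tracked chloroplast centres.
#' @param AUm2 cell area A in µm².
#' @param dUm adjacency distance d in µm (default 3 = 2 x 1.5).
#' @param overlapCorrect estimate the chloroplast-adjacent area as the
#'   union of the adjacency discs (grid approximation) instead of the
#'   per-chloroplast sum. Off by default.
#' @param gridStepUm grid resolution for the overlap correction, µm.
#' @return A list: `meanE`, `perFrame` (data.frame frame, N, Nc, Ac, E),
#'   `dUm`, `AUm2`, `nUndefinedFrames`.
#' @examples
#' # one chloroplast at the origin, 10 mitochondria of which 2 adjacent
#' m <- TrajectorySet(data.frame(track_id = 0:9, frame = 0L,
#'                               x = c(1, 2, seq(20, 27)), y = 0),
#'                    frameIntervalS = 1)
#' c1 <- TrajectorySet(data.frame(track_id = 0L, frame = 0L, x = 0, y = 0),
#'                     frameIntervalS = 1, nFrames = 1L,
#'                     organelleKind = "chloroplast")
#' chloroplastEnrichment(m, c1, AUm2 = 1000)$meanE  # about 8.59
#' @export
chloroplastEnrichment <- function(mitoTs, chloroTs, AUm2, dUm = 3,
                                  overlapCorrect = FALSE,
                                  gridStepUm = 0.05) {
  stopifnot(is(mitoTs, "TrajectorySet"), is(chloroTs, "TrajectorySet"))
  stopifnot(AUm2 > 0, dUm > 0)
  mitoFrames <- .splitByFrame(mitoTs@spots)
  chloroFrames <- .splitByFrame(chloroTs@spots)
  if (!length(chloroFrames)) {
    warning("enrichment undefined: chloroplast set has no spots")
    return(list(meanE = NA_real_,
                perFrame = data.frame(frame = integer(), N = integer(),
                                      Nc = integer(), Ac = numeric(),
                                      E = numeric()),
                dUm = dUm, AUm2 = AUm2, nUndefinedFrames = 0L))
  }
  rows <- lapply(mitoFrames, function(fr) {
    f <- fr$frame[1L]
    ch <- chloroFrames[[as.character(f)]]
    N <- nrow(fr)
    if (is.null(ch) || !nrow(ch)) {
      return(data.frame(frame = f, N = N, Nc = NA_integer_,
                        Ac = NA_real_, E = NA_real_))
    }
    dmat <- outer(fr$x, ch$x, "-")^2 + outer(fr$y, ch$y, "-")^2
    nearest <- sqrt(apply(dmat, 1L, min))
    Nc <- sum(nearest <= dUm)
    Ac <- if (overlapCorrect) {
      .discUnionArea(cbind(ch$x, ch$y), dUm, gridStepUm)
    } else {
      nrow(ch) * pi * dUm^2
    }
    E <- if (Ac >= AUm2 || N - Nc == 0L) {
      NA_real_  # undefined: no non-adjacent area or no non-adjacent mitos
    } else {
      (Nc / Ac) / ((N - Nc) / (AUm2 - Ac))
    }
    data.frame(frame = f, N = N, Nc = Nc, Ac = Ac, E = E)
  })
  perFrame <- do.call(rbind, rows)
  rownames(perFrame) <- NULL
  nUndef <- sum(is.na(perFrame$E))
  if (nUndef) {
    warning(nUndef, " frame(s) with undefined enrichment excluded from mean")
  }
  defined <- perFrame$E[!is.na(perFrame$E)]
  list(meanE = if (length(defined)) mean(defined) else NA_real_,
       perFrame = perFrame, dUm = dUm, AUm2 = AUm2,
       nUndefinedFrames = nUndef)
}

# Grid approximation of the area of a union of discs of radius r.
.discUnionArea <- function(centres, r, step) {
  xr <- range(centres[, 1L]) + c(-r, r)
  yr <- range(centres[, 2L]) + c(-r, r)
  gx <- seq(xr[1L], xr[2L], by = step)
  gy <- seq(yr[1L], yr[2L], by = step)
  inside <- matrix(FALSE, length(gx), length(gy))
  for (k in seq_len(nrow(centres))) {
    inside <- inside |
      (outer((gx - centres[k, 1L])^2, (gy - centres[k, 2L])^2, "+") <= r^2)
  }
  sum(inside) * step^2
}
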