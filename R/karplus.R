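#' Karplus parameters for 3J(HN-HA)
#'
#' The Vuister-Bax parameterisation `J = A cos^2(phi - 60) + B cos(phi - 60)
#' + C` with A = 6.51, B = -1.76, C = 1.60 Hz and a -60 degree phase offset.
#'
#' @param A,B,C Karplus coefficients in Hz.
#' @param phase phase offset in degrees added to phi inside the cosine
#'   (default -60).
#' @return parameter list.
#' @export
karplus_params <- function(A = 6.51, B = -1.76, C = 1.60, phase = -60) {
  list(A = A, B = B, C = C, phase = phase)
}

#' Karplus 3J(HN-HA) coupling from the phi dihedral
#'
#' @param phi backbone phi angle(s) in degrees (vectorised).
#' @param params a [karplus_params()] list.
#' @return coupling constant(s) in Hz. 360-degree periodic in `phi`.
#' @examples
#' karplus_j(150)   # cos term vanishes -> C = 1.60 Hz
#' karplus_j(-57)   # canonical alpha helix -> ~3.74 Hz
#' @export
karplus_j <- function(phi, params = karplus_params()) {
  ct <- cos(deg2rad(phi + params$phase))
  params$A * ct^2 + params$B * ct + params$C
}

#' Analytic bounds of the Karplus curve
#'
#' Extrema of the quadratic in `cos(theta)` over `theta`, used as a sanity
#' envelope for predicted couplings.
#'
#' @param params a [karplus_params()] list.
#' @return numeric `c(min, max)` in Hz.
#' @export
karplus_bounds <- function(params = karplus_params()) {
  f <- function(ct) params$A * ct^2 + params$B * ct + params$C
  cand <- c(-1, 1)
  if (abs(params$A) > 0) {
    v <- -params$B / (2 * params$A)
    if (v >= -1 && v <= 1) cand <- c(cand, v)
  }
  range(f(cand))
}

#' Per-residue 3J(HN-HA) coupling profile
#'
#' Ensemble average of the per-frame coupling (the average of J over frames,
#' not J of the average phi: under fast exchange NMR measures the population
#' average of J). The spread is estimated as the standard deviation across
#' `n_windows` contiguous windows of the frame range when requested.
#'
#' @param dihedrals an `mh_dihedrals` object.
#' @param frames frame range (see [resolve_frames()]).
#' @param params Karplus parameters.
#' @param n_windows number of contiguous windows for the sd estimate
#'   (default 5); `NULL` for a plain per-frame sd.
#' @param average `"per-frame"` (default) averages J over frames;
#'   `"mean-phi"` evaluates J at the circular-mean phi instead.
#' @return data.frame with `resseq`, `mean_j`, `sd`, `n_frames`; residues
#'   with undefined phi are omitted.
#' @export
j_profile <- function(dihedrals, frames = NULL, params = karplus_params(),
                      n_windows = 5L, average = c("per-frame", "mean-phi")) {
  average <- match.arg(average)
  fr <- resolve_frames(ncol(dihedrals$phi), frames)
  phi <- dihedrals$phi[, fr, drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(phi))) {
    v <- phi[i, ]
    ok <- !is.na(v)
    if (!any(ok)) next
    if (average == "per-frame") {
      j <- karplus_j(v[ok], params)
      mj <- mean(j)
      sdj <- if (!is.null(n_windows) && sum(ok) >= n_windows) {
        wm <- block_average(karplus_j(v[ok], params), n_windows)
        stats::sd(wm)
      } else stats::sd(j)
    } else {
      th <- deg2rad(v[ok])
      mphi <- rad2deg(atan2(mean(sin(th)), mean(cos(th))))
      mj <- karplus_j(mphi, params)
      sdj <- NA_real_
    }
    out[[length(out) + 1L]] <- data.frame(
      resseq = dihedrals$resseq[i], mean_j = mj, sd = sdj, n_frames = sum(ok))
  }
  do.call(rbind, out)
}
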