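#' Background removal by proper orthogonal decomposition
#'
#' Decomposes the image time series into orthogonal spatial modes and
#' discards the leading (most energetic) ones, which in brightfield
#' recordings of a beating heart carry the static background and slow
#' artifacts; the retained trailing modes carry the moving red blood
#' corpuscle patterns that the correlation engine tracks.
#'
#' Modes are removed up to the first one whose cumulative energy (squared
#' singular value fraction) reaches `energy_cutoff`; alternatively a fixed
#' number of leading modes can be named via `n_modes`.
#'
#' @param stack an [image_stack] with at least 3 frames.
#' @param energy_cutoff cumulative-energy fraction at which leading modes
#'   stop being discarded (0 < cutoff < 1, default 0.90).
#' @param n_modes optional integer: discard exactly this many leading
#'   modes, overriding `energy_cutoff`.
#' @return the filtered [image_stack]; attribute `"pod"` records the mode
#'   energies and the number of modes removed.
#' @export
pod_background_removal <- function(stack, energy_cutoff = 0.90, n_modes = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  if (d[3] < 3) stop("POD filtering needs at least 3 frames")
  if (is.null(n_modes) && (energy_cutoff <= 0 || energy_cutoff >= 1))
    stop("`energy_cutoff` must lie strictly between 0 and 1")
  X <- matrix(stack$frames, d[1] * d[2], d[3])
  G <- crossprod(X)                     # nt x nt temporal Gram matrix
  tot <- sum(diag(G))
  if (tot <= .Machine$double.eps * d[1] * d[2] * d[3])
    stop("degenerate decomposition: the stack has no intensity energy; ",
         "check that frames were loaded correctly")
  e <- eigen(G, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  energy <- ev / sum(ev)
  cum_energy <- cumsum(energy)
  k <- if (!is.null(n_modes)) as.integer(n_modes)
       else which(cum_energy >= energy_cutoff)[1]
  k <- min(max(k, 1L), d[3] - 1L)
  if (cum_energy[k] > 1 - 1e-10)
    warning("degenerate decomposition: no temporal fluctuation beyond the ",
            "removed modes (are all frames identical?); output is ~zero")
  Vk <- e$vectors[, seq_len(k), drop = FALSE]
  Xout <- X - (X %*% Vk) %*% t(Vk)      # project out the leading modes
  out <- stack
  out$frames <- array(Xout, d)
  attr(out, "pod") <- list(energy = energy, removed = k,
                           cumulative_energy = cum_energy[k])
  out
}
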