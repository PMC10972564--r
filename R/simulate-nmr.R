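## Simulation of 2D methyl HMQC peak tables under slow conformational
## exchange.

## evaluate expr with a private, seeded RNG stream, restoring the
## caller's RNG state afterwards
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a methyl HMQC peak table
#'
#' For probes in slow exchange the R- and L-state peaks are resolved and
#' their volumes are proportional to the state populations, so an
#' exchange reporter contributes two rows whose noiseless volume ratio is
#' exactly \code{pR : pL} (with the inhibitor-bound population where a
#' compound is present).  Single-peak probes contribute one row at their
#' (possibly inhibitor-displaced) position; probes broadened by the bound
#' inhibitor contribute rows with volume 0.  Total volume per probe is 1
#' before noise.  Volume noise is additive Gaussian (sd =
#' \code{noiseSd}, on the unit-total-volume scale) clamped at zero; peak
#' positions are noiseless.
#'
#' @param probes list of \code{\linkS4class{MethylProbe}} objects.
#' @param model apo \code{\linkS4class{ConformerModel}}.
#' @param inhibitor optional \code{\linkS4class{InhibitorSpec}}.
#' @param noiseSd volume noise standard deviation (0 = deterministic,
#'   seed-independent output).
#' @param seed integer seed used when \code{noiseSd > 0}; the caller's
#'   RNG state is untouched.
#' @return data.frame with columns probe_id, state ("R" or "L"), h_ppm,
#'   c_ppm, volume.
#' @examples
#' simulateHmqcPeakPairs(defaultMethylProbes()[1:3], ConformerModel(0.8))
#' @export
simulateHmqcPeakPairs <- function(probes = defaultMethylProbes(), model,
                                  inhibitor = NULL, noiseSd = 0,
                                  seed = 1L) {
  rows <- lapply(probes, function(pr) {
    if (identical(pr@category, "EXCHANGE_REPORTER")) {
      p <- effectivePR(model, inhibitor)
      data.frame(probe_id = pr@probeId, state = c("R", "L"),
                 h_ppm = c(pr@shiftR[1], pr@shiftL[1]),
                 c_ppm = c(pr@shiftR[2], pr@shiftL[2]),
                 volume = c(p, 1 - p), stringsAsFactors = FALSE)
    } else {
      pos <- boundPosition(pr, model, inhibitor)
      vol <- if (isBroadened(pr, inhibitor)) 0 else 1
      data.frame(probe_id = pr@probeId, state = "R",
                 h_ppm = pos[1], c_ppm = pos[2], volume = vol,
                 stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (noiseSd > 0) {
    tab$volume <- withSeed(seed, {
      noisy <- tab$volume + stats::rnorm(nrow(tab), 0, noiseSd)
      noisy[tab$volume == 0] <- 0          # broadened peaks stay absent
      pmax(noisy, 0)
    })
  }
  tab
}
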