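#' Canonical sensorimotor sub-bands
#'
#' The six logarithmically scaled sub-bands used throughout the pipeline:
#' low/high beta (`beta_l`: 12-21 Hz, `beta_h`: 21-35 Hz), low/high gamma
#' (`gamma_l`: 35-50 Hz, `gamma_h`: 50-70 Hz) and low/high high-gamma
#' (`Gamma_l`: 70-99 Hz, `Gamma_h`: 99-140 Hz).
#'
#' @return A data.frame with columns `band`, `f_lo`, `f_hi` (Hz) and `group`
#'   (`"beta"`, `"gamma"` or `"Gamma"`).
#' @examples
#' subbands()
#' @export
subbands <- function() {
  data.frame(
    band  = c("beta_l", "beta_h", "gamma_l", "gamma_h", "Gamma_l", "Gamma_h"),
    f_lo  = c(12, 21, 35, 50, 70, 99),
    f_hi  = c(21, 35, 50, 70, 99, 140),
    group = c("beta", "beta", "gamma", "gamma", "Gamma", "Gamma"),
    stringsAsFactors = FALSE
  )
}

#' Merged band table
#'
#' The three merged bands obtained by averaging instantaneous bandpower over
#' each low/high sub-band pair: beta 12-35 Hz, gamma 35-70 Hz and
#' high-gamma (Gamma) 70-140 Hz.
#'
#' @return A data.frame with columns `band`, `lo_member`, `hi_member`,
#'   `f_lo`, `f_hi`.
#' @export
merged_bands <- function() {
  data.frame(
    band      = c("beta", "gamma", "Gamma"),
    lo_member = c("beta_l", "gamma_l", "Gamma_l"),
    hi_member = c("beta_h", "gamma_h", "Gamma_h"),
    f_lo      = c(12, 35, 70),
    f_hi      = c(35, 70, 140),
    stringsAsFactors = FALSE
  )
}

band_row <- function(band) {
  sb <- subbands()
  i <- match(band, sb$band)
  if (is.na(i)) stop("unknown sub-band: ", band, call. = FALSE)
  sb[i, ]
}
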