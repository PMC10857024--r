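# Independent arithmetic oracles for every vegetation index, hand-written
# from the published formula tables. They take plain named reflectance /
# channel values and share no code with the package registry.

svi_oracles <- list(
  NDVI    = function(R) (R[["750"]] - R[["705"]]) / (R[["750"]] + R[["705"]]),
  NDVI1   = function(R) (R[["750"]] - R[["680"]]) / (R[["750"]] + R[["680"]]),
  NDVI3D  = function(R) (R[["780"]] - R[["715"]]) / (R[["780"]] + R[["715"]]),
  VOG2    = function(R) R[["740"]] / R[["720"]],
  MSR1    = function(R) (R[["750"]] - R[["445"]]) / (R[["705"]] - R[["445"]]),
  SIPI    = function(R) (R[["800"]] - R[["445"]]) / (R[["800"]] - R[["680"]]),
  MDATT1  = function(R) (R[["703"]] - R[["732"]]) / (R[["703"]] - R[["722"]]),
  MCARI   = function(R) ((R[["702"]] - R[["671"]]) - 0.2 * (R[["702"]] - R[["549"]])) *
                        (R[["702"]] / R[["671"]]),
  GRVI    = function(R) R[["872"]] / R[["559"]],
  PRI     = function(R) (R[["531"]] - R[["570"]]) / (R[["531"]] + R[["570"]]),
  VARI    = function(R) (R[["559"]] - R[["661"]]) / (R[["559"]] + R[["661"]] - R[["488"]]),
  VREI    = function(R) R[["740"]] / R[["720"]],
  SR      = function(R) R[["810"]] / R[["550"]],
  RVSI    = function(R) 0.5 * (R[["722"]] + R[["763"]]) - R[["733"]],
  BGI1    = function(R) R[["450"]] / R[["550"]],
  Lic2    = function(R) (R[["790"]] - R[["680"]]) / (R[["790"]] + R[["680"]]),
  PSRI    = function(R) (R[["680"]] - R[["500"]]) / R[["750"]],
  NPCI    = function(R) (R[["642"]] - R[["432"]]) / (R[["642"]] + R[["432"]]),
  CIgreen = function(R) R[["780"]] / R[["550"]] - 1
)

cvi_oracles <- list(
  rn   = function(R, G, B) R / (R + G + B),
  gn   = function(R, G, B) G / (R + G + B),
  bn   = function(R, G, B) B / (R + G + B),
  GRRI = function(R, G, B) G / R,
  RBRI = function(R, G, B) R / B,
  GBRI = function(R, G, B) G / B,
  IKAW = function(R, G, B) (R - B) / (R + B),
  NDI  = function(R, G, B) {
    rn <- R / (R + G + B); gn <- G / (R + G + B)
    (rn - gn) / (rn + gn + 0.01)
  },
  WI   = function(R, G, B) (G - B) / (R - G),
  GLI  = function(R, G, B) (2 * G - R - B) / (2 * G + R + B)
)

# All bands any spectral oracle reads, for building exact-hit test spectra.
svi_oracle_bands <- sort(unique(c(432, 445, 450, 488, 500, 531, 549, 550, 559,
                                  570, 642, 661, 671, 680, 702, 703, 705, 715,
                                  720, 722, 732, 733, 740, 750, 763, 780, 790,
                                  800, 810, 872)))

random_band_spectrum <- function() {
  leaf_spectrum(svi_oracle_bands,
                stats::runif(length(svi_oracle_bands), 0.01, 1))
}
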