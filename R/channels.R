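# DEAP channel layout (Geneva ordering of the 32-channel 10/20 montage,
# followed by the eight peripheral channels).

#' DEAP channel labels
#'
#' The 32 EEG channels in DEAP order, optionally followed by the eight
#' peripheral (non-EEG) channels that DEAP records alongside them.
#'
#' @param peripheral include the eight peripheral labels.
#' @return character vector of length 32 or 40.
#' @export
deap_channel_labels <- function(peripheral = FALSE) {
  eeg <- c(
    "Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
    "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
    "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC2", "Cz",
    "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2"
  )
  if (!peripheral) return(eeg)
  c(eeg, c("hEOG", "vEOG", "zEMG", "tEMG", "GSR", "RESP", "PLET", "TEMP"))
}

# Homologous frontal pair carrying the latent-valence alpha asymmetry.
asymmetry_pair <- function() c(left = "F3", right = "F4")
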