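#' The fixed 96-channel single-base-substitution layout
#'
#' Channel order is substitution-class major: the six pyrimidine-strand
#' substitution classes (C>A, C>G, C>T, T>A, T>C, T>G), each expanded over
#' the 16 combinations of 5' flanking base (A, C, G, T) by 3' flanking base
#' (A, C, G, T). Channel indices used elsewhere in the package are 0-based
#' (0-95) so that spectra files interchange cleanly with other tooling.
#'
#' @return Character vector of 96 channel names, e.g. `"A[C>A]A"`.
#' @export
sbs96_channels <- function() {
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(96)
  i <- 1L
  for (cl in classes) {
    for (five in bases) {
      for (three in bases) {
        out[i] <- paste0(five, "[", cl, "]", three)
        i <- i + 1L
      }
    }
  }
  out
}

#' The 32 pyrimidine-centred trinucleotide contexts
#'
#' @return Character vector of 32 trinucleotides (centre base C or T).
#' @export
trinuc32_contexts <- function() {
  bases <- c("A", "C", "G", "T")
  out <- character(32)
  i <- 1L
  for (centre in c("C", "T")) {
    for (five in bases) {
      for (three in bases) {
        out[i] <- paste0(five, centre, three)
        i <- i + 1L
      }
    }
  }
  out
}

#' Map each of the 96 channels to its trinucleotide context
#'
#' @return Integer vector of length 96; entry j is the index (1-32) into
#'   [trinuc32_contexts()] of the context of channel j.
#' @export
channel_to_context <- function() {
  ch <- sbs96_channels()
  ref <- substr(ch, 3, 3)
  five <- substr(ch, 1, 1)
  three <- substr(ch, 7, 7)
  match(paste0(five, ref, three), trinuc32_contexts())
}

#' Reference and alternate base for each channel
#'
#' @return Data frame with columns `channel` (0-based index), `name`,
#'   `ref`, `alt`, `context`.
#' @keywords internal
channel_table <- function() {
  ch <- sbs96_channels()
  data.frame(
    channel = 0:95,
    name = ch,
    ref = substr(ch, 3, 3),
    alt = substr(ch, 5, 5),
    context = trinuc32_contexts()[channel_to_context()],
    stringsAsFactors = FALSE
  )
}

#' Validate a 96-channel probability vector
#' @keywords internal
check_signature_vector <- function(p, name = "signature") {
  if (length(p) != 96L) {
    stop(name, " must have length 96, got ", length(p))
  }
  if (any(p < 0)) stop(name, " has negative entries")
  if (abs(sum(p) - 1) > 1e-9) {
    stop(name, " must sum to 1 within 1e-9 (sum = ", format(sum(p)), ")")
  }
  invisible(p)
}

#' Built-in synthetic mutational signatures
#'
#' A small set of 96-channel probability profiles constructed analytically
#' for simulation and testing. They are synthetic: shaped to resemble the
#' qualitative character of processes seen in blood (a clock-like profile
#' with CpG C>T enrichment, a flat profile, alkylating-agent-like T>A
#' dominance, platinum-like C>A/C>T skew, a thymine-focused antimetabolite
#' profile), but they are not COSMIC reference signatures and carry no
#' external provenance.
#'
#' @return Named list of 96-channel probability vectors:
#'   `sig_clock`, `sig_flat`, `sig_alkyl`, `sig_platinum`, `sig_thymine`.
#' @export
example_signatures <- function() {
  ch <- channel_table()
  cls <- paste0(ch$ref, ">", ch$alt)

  # clock-like: flat background with strong C>T at NCG contexts
  clock <- rep(0.3, 96)
  clock[cls == "C>T"] <- 1
  clock[cls == "C>T" & substr(ch$context, 3, 3) == "G"] <- 12
  clock <- clock / sum(clock)

  flat <- rep(1 / 96, 96)

  # alkylating-like: dominated by T>A with 5' purine preference
  alkyl <- rep(0.05, 96)
  alkyl[cls == "T>A"] <- 4
  alkyl[cls == "T>A" & substr(ch$context, 1, 1) %in% c("A", "G")] <- 10
  alkyl[cls == "T>C"] <- 1
  alkyl <- alkyl / sum(alkyl)

  # platinum-like: C>A and C>T at CC dinucleotides
  plat <- rep(0.05, 96)
  plat[cls == "C>A"] <- 4
  plat[cls == "C>T" & substr(ch$context, 1, 1) == "C"] <- 8
  plat <- plat / sum(plat)

  # antimetabolite-like: T>G with 3' T preference, plus some T>C
  thy <- rep(0.03, 96)
  thy[cls == "T>G"] <- 5
  thy[cls == "T>G" & substr(ch$context, 3, 3) == "T"] <- 14
  thy[cls == "T>C"] <- 1.5
  thy <- thy / sum(thy)

  sigs <- list(
    sig_clock = clock, sig_flat = flat, sig_alkyl = alkyl,
    sig_platinum = plat, sig_thymine = thy
  )
  for (nm in names(sigs)) check_signature_vector(sigs[[nm]], nm)
  sigs
}
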