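#' The 50-measure parameter catalogue
#'
#' The fixed catalogue of vibratory measures computed on the glottal area
#' waveform: 41 measures on the total waveform and 9 left-right symmetry
#' measures on the partials, grouped into seven families. 15 measures are
#' mathematically dependent on (or near-linear in) other catalogue members
#' and carry an exclusion flag: they are computed and reported but left out
#' of the main statistical analysis, so 35 relevant measures remain with
#' per-group relevant sizes FPM 1, PPM 6, APM 7, EPM 4, SM 7, GDC 5, MM 5.
#'
#' @return A data frame with columns `name`, `group`, `excluded`, `units`.
#' @export
parameter_catalogue <- function() {
  entry <- function(name, group, excluded, units) {
    data.frame(name = name, group = group, excluded = excluded, units = units)
  }
  rbind(
    entry("F0",      "FPM", FALSE, "Hz"),
    entry("MCD",     "FPM", TRUE,  "ms"),
    entry("TP",      "PPM", FALSE, "ratio"),
    entry("MJit",    "PPM", FALSE, "ms"),
    entry("PPQ3",    "PPM", FALSE, "%"),
    entry("PPQ5",    "PPM", FALSE, "%"),
    entry("PPQ11",   "PPM", FALSE, "%"),
    entry("PVI",     "PPM", FALSE, "1"),
    entry("Jit(%)",  "PPM", TRUE,  "%"),
    entry("JitFac",  "PPM", TRUE,  "%"),
    entry("JitRat",  "PPM", TRUE,  "1"),
    entry("PPF",     "PPM", TRUE,  "%"),
    entry("RAPB",    "PPM", TRUE,  "%"),
    entry("RAPK",    "PPM", TRUE,  "%"),
    entry("AP",      "APM", FALSE, "ratio"),
    entry("MShim",   "APM", FALSE, "dB"),
    entry("Shim(%)", "APM", FALSE, "%"),
    entry("APQ3",    "APM", FALSE, "%"),
    entry("APQ5",    "APM", FALSE, "%"),
    entry("APQ11",   "APM", FALSE, "%"),
    entry("AVI",     "APM", FALSE, "dB"),
    entry("APF",     "APM", TRUE,  "%"),
    entry("EPQ3",    "EPM", FALSE, "%"),
    entry("EPQ5",    "EPM", FALSE, "%"),
    entry("EPQ11",   "EPM", FALSE, "%"),
    entry("EPF",     "EPM", FALSE, "%"),
    entry("AmSI",    "SM",  FALSE, "ratio"),
    entry("AmS",     "SM",  FALSE, "ratio"),
    entry("WaSI",    "SM",  FALSE, "ratio"),
    entry("PhAI",    "SM",  FALSE, "ratio"),
    entry("PhA",     "SM",  FALSE, "ratio"),
    entry("SpSI",    "SM",  FALSE, "ratio"),
    entry("SpS",     "SM",  FALSE, "ratio"),
    entry("DyRSI",   "SM",  TRUE,  "ratio"),
    entry("DyRS",    "SM",  TRUE,  "ratio"),
    entry("OQ",      "GDC", FALSE, "ratio"),
    entry("CQ",      "GDC", FALSE, "ratio"),
    entry("PQ",      "GDC", FALSE, "ratio"),
    entry("GAI",     "GDC", FALSE, "ratio"),
    entry("GGI",     "GDC", FALSE, "ratio"),
    entry("SQ",      "GDC", TRUE,  "ratio"),
    entry("SI",      "GDC", TRUE,  "ratio"),
    entry("RQ",      "GDC", TRUE,  "ratio"),
    entry("AQ",      "GDC", TRUE,  "ratio"),
    entry("MADR",    "MM",  FALSE, "Mpx/s"),
    entry("AmQ",     "MM",  FALSE, "s"),
    entry("Stiff",   "MM",  FALSE, "1/s"),
    entry("PCV",     "MM",  FALSE, "Mpx/s"),
    entry("ALR",     "MM",  FALSE, "ratio"),
    entry("PA",      "MM",  TRUE,  "px/s^2")
  )
}
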