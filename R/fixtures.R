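fixture_path <- function(name) {
  system.file("extdata", name, package = "pkdeplete", mustWork = TRUE)
}

#' Donkey plasma concentration fixtures
#'
#' Transcription of the published mean plasma concentration-time table
#' for ABZSO and its sulfone metabolite after a single intramuscular
#' dose of 7.5 mg/kg (n = 5 donkeys, 0.25-72 h). The sulfone is
#' non-detected at 0.25 and 0.5 h and both analytes at 72 h; those
#' entries are censored at the plasma LOD.
#'
#' @return Named list of [conc_series]: `ABZSO`, `ABZSO2`.
#' @export
donkey_plasma <- function() {
  read_concentration_csv(fixture_path("donkey_plasma.csv"),
                         dose = 7.5,
                         schedule = "single IM dose, 7.5 mg/kg BW")$plasma
}

#' Donkey tissue residue fixtures
#'
#' Transcriptions of the published mean residue tables for liver,
#' kidney, skin and muscle after three consecutive daily intramuscular
#' doses of 7.5 mg/kg (n = 5, 4-240 h after the last dose), including
#' the printed "total concentration" column (`analyte = "total"`) kept
#' as transcribed for cross-checks, not recomputed.
#'
#' Known transcription caveats carried as printed: the kidney totals at
#' 4 and 8 h disagree with their component sums by 0.16 and 0.03 ug/g
#' (use [check_total_consistency] to flag them), and the skin sulfone SD
#' at 8 h was printed "032", transcribed here as 0.32.
#'
#' @param tissue One of `"liver"`, `"kidney"`, `"skin"`, `"muscle"`, or
#'   `NULL` for all.
#' @return For one tissue, a named list of [conc_series] (`ABZSO`,
#'   `ABZSO2`, `ABZSO2NH2`, `total`); otherwise a named list of such
#'   lists.
#' @export
donkey_residues <- function(tissue = NULL) {
  tis <- read_concentration_csv(fixture_path("donkey_tissues.csv"),
                                dose = 7.5,
                                schedule = "IM, 7.5 mg/kg BW daily for 3 days")$tissues
  if (is.null(tissue)) return(tis)
  tissue <- match.arg(tissue, names(tis))
  tis[[tissue]]
}

#' Assay detection limits
#'
#' Limits of detection of the HPLC-UV assay per analyte and matrix
#' (ug/mL for plasma, ug/g for tissues), used for censoring in the
#' simulators and carried on the fixtures.
#'
#' @return Data frame with columns `matrix`, `analyte`, `lod`.
#' @export
donkey_lods <- function() {
  utils::read.csv(fixture_path("donkey_lod.csv"), stringsAsFactors = FALSE)
}

#' Published primary pharmacokinetic parameters
#'
#' The study's reported one-compartment primary triples (means over the
#' five per-animal fits): zero-time intercept `M` (printed as "A"),
#' absorption and elimination rate constants, and the parent dose.
#' Useful as ground truth for simulations and as input for the
#' closed-form secondary parameters.
#'
#' @return Named list of [pk_params]: `ABZSO`, `ABZSO2`.
#' @export
donkey_pk_reference <- function() {
  df <- utils::read.csv(fixture_path("donkey_pk_reference.csv"),
                        stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    pk_params(df$M[i], df$Ka[i], df$Ke[i], df$dose_mg_kg[i]))
  names(out) <- df$analyte
  out
}

#' Complete donkey study bundle
#'
#' Plasma and tissue fixtures assembled into one `study_bundle`, ready
#' for [run_pipeline].
#'
#' @return A `study_bundle`.
#' @export
donkey_study <- function() {
  study_bundle(plasma = donkey_plasma(),
               tissues = donkey_residues(),
               dose = 7.5,
               schedule = "PK: single IM 7.5 mg/kg; residues: 3 daily IM doses",
               metadata = list(species = "donkey", route = "IM"))
}
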