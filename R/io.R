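#' @keywords internal
"_PACKAGE"

#' @import rlang
#' @importFrom dplyr %>% arrange bind_rows case_when filter group_by left_join
#'   mutate n rename select summarise ungroup across all_of
#' @importFrom tibble tibble as_tibble
#' @importFrom stats lm coef predict t.test uniroot optim median quantile
#'   sd rnorm qt confint setNames complete.cases
#' @importFrom generics tidy glance augment
NULL

# canonical record fields every downstream estimator relies on
.gasex_mandatory <- c("An", "Ca", "Ci_raw", "gsw", "El", "Wi", "Wa",
                      "PPFD", "Tleaf_C")
.gasex_optional <- c("O2_frac", "Ft", "Fm_prime", "genotype", "plant_id",
                     "day", "curve_id")

#' Read a gas-exchange + fluorescence table
#'
#' Reads a delimited text export (LI-6800 style, one header row) into the
#' canonical record tibble used by every estimator in the package.
#' Columns are mapped to canonical names through `column_map`; unknown
#' extra columns are carried along untouched. Internal units are mol, m,
#' s and umol mol-1 for CO2: flux columns exported in mmol m-2 s-1 can be
#' declared in `unit_hints` and are divided by 1000 on ingest. Rows
#' violating physical invariants (non-finite An, Ca <= 0, Wi < Wa,
#' negative conductance/transpiration/PPFD, or fluorescence with
#' Fm' <= Ft) are dropped with a warning naming the row numbers.
#'
#' @param path Path to a CSV/TSV file with a single header row.
#' @param column_map Named character vector mapping canonical field names
#'   to file headers, e.g. `c(An = "A", Ca = "CO2_r", ...)`. Must cover
#'   `An, Ca, Ci_raw, gsw, El, Wi, Wa, PPFD, Tleaf_C`; may also map
#'   `O2_frac, Ft, Fm_prime, genotype, plant_id, day, curve_id`.
#'   Canonical names used directly as headers need no entry.
#' @param unit_hints Named character vector, canonical field ->
#'   `"mmol"` for columns exported in mmol that must be rescaled to mol
#'   (e.g. `c(El = "mmol")`).
#' @param delim Field delimiter, default `","`.
#'
#' @return A tibble with one row per retained record, canonical columns
#'   first, extra file columns preserved.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(
#'   A = c(18.2, 12.1), CO2_r = 400, Ci = c(280, 300), gsw = 0.3,
#'   E = 0.004, Wi = 0.03, Wa = 0.012, Qin = 1500, Tleaf = 30
#' ), f, row.names = FALSE)
#' read_gasex_table(f, column_map = c(
#'   An = "A", Ca = "CO2_r", Ci_raw = "Ci", El = "E",
#'   PPFD = "Qin", Tleaf_C = "Tleaf"
#' ))
read_gasex_table <- function(path, column_map = character(),
                             unit_hints = character(), delim = ",") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  # default mapping: canonical name used verbatim in the file
  known <- c(.gasex_mandatory, .gasex_optional)
  map <- setNames(known, known)
  map[names(column_map)] <- unname(column_map)
  missing_cols <- setdiff(.gasex_mandatory,
                          names(map)[map %in% names(raw)])
  if (length(missing_cols) > 0) {
    stop("mandatory column(s) not found in file: ",
         paste0(missing_cols, " (mapped to '", map[missing_cols], "')",
                collapse = ", "), call. = FALSE)
  }
  present <- map[map %in% names(raw)]
  out <- raw
  names(out)[match(present, names(out))] <- names(present)

  numeric_fields <- intersect(
    c(.gasex_mandatory, "O2_frac", "Ft", "Fm_prime", "day"), names(out))
  for (f in numeric_fields) {
    v <- out[[f]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad) > 0) {
        stop("non-numeric value(s) in column '", f, "' at row(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      out[[f]] <- conv
    }
  }
  for (f in intersect(names(unit_hints), names(out))) {
    if (identical(unit_hints[[f]], "mmol")) out[[f]] <- out[[f]] / 1000
  }
  if (!"O2_frac" %in% names(out)) out$O2_frac <- 0.21

  keep <- validate_gasex(out)
  dropped <- which(!keep)
  if (length(dropped) > 0) {
    warning("excluded ", length(dropped),
            " row(s) failing record invariants: rows ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  canon <- intersect(c(.gasex_mandatory, .gasex_optional), names(out))
  out <- out[keep, c(canon, setdiff(names(out), canon)), drop = FALSE]
  as_tibble(out)
}

# TRUE for rows satisfying the record invariants; fluorescence checked
# only where both Ft and Fm' are present
validate_gasex <- function(df) {
  ok <- is.finite(df$An) & is.finite(df$Ca) & df$Ca > 0 &
    is.finite(df$Wi) & is.finite(df$Wa) & df$Wi >= df$Wa & df$Wa >= 0 &
    is.finite(df$gsw) & df$gsw >= 0 & is.finite(df$El) & df$El >= 0 &
    is.finite(df$PPFD) & df$PPFD >= 0
  if ("O2_frac" %in% names(df)) {
    ok <- ok & df$O2_frac > 0 & df$O2_frac <= 0.25
  }
  if (all(c("Ft", "Fm_prime") %in% names(df))) {
    has_fl <- is.finite(df$Ft) & is.finite(df$Fm_prime)
    ok <- ok & (!has_fl | (df$Fm_prime > df$Ft & df$Ft > 0))
  }
  ok & !is.na(ok)
}

#' Relative soil water content by lysimetry
#'
#' `RSWC (%) = (PW - DW) / (t0W - DW) * 100`, where `PW` is the current
#' pot weight, `DW` the pot dry weight and `t0W` the pot weight on day 0
#' of the drydown. Vectorised over `PW`.
#'
#' @param PW Current pot weight (kg).
#' @param DW Pot dry weight (kg).
#' @param t0W Pot weight on day 0 (kg).
#' @return RSWC in percent. Values above 100 (pot heavier than day 0)
#'   are returned with a warning; `PW < DW` is rejected.
#' @export
#' @examples
#' compute_rswc(PW = 8, DW = 5, t0W = 10) # 60
compute_rswc <- function(PW, DW, t0W) {
  stopifnot(is.numeric(PW), is.numeric(DW), is.numeric(t0W))
  if (any(t0W <= DW)) {
    stop("t0W must exceed DW (t0W = DW gives division by zero)",
         call. = FALSE)
  }
  if (any(DW <= 0)) stop("DW must be positive", call. = FALSE)
  if (any(PW < DW)) {
    stop("PW < DW: pot cannot weigh less than its dry weight",
         call. = FALSE)
  }
  rswc <- 100 * (PW - DW) / (t0W - DW)
  if (any(rswc > 100)) {
    warning("RSWC above 100%: pot heavier than on day 0", call. = FALSE)
  }
  rswc
}
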