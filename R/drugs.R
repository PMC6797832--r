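## Compound pharmacology: Hill-equation channel block, static hERG block,
## conductance scaling, drug tables, and the embedded 28-compound CiPA
## reference table (per-drug metric values and risk labels).

#' Hill-equation channel block
#'
#' Percent block of a channel current at drug concentration `C`:
#' \eqn{100 \, C^h / (IC_{50}^h + C^h)}.
#'
#' @param C Drug concentration (same unit as `IC50`), `>= 0`.
#' @param IC50 Half-block concentration, `> 0`.
#' @param h Hill coefficient, `> 0`.
#' @return Percent block in `[0, 100)`, monotone increasing in `C`.
#' @export
hill_block <- function(C, IC50, h) {
  if (any(IC50 <= 0)) stop("IC50 must be positive")
  if (any(h <= 0)) stop("Hill coefficient must be positive")
  if (any(C < 0)) stop("concentration must be non-negative")
  100 * C^h / (IC50^h + C^h)
}

#' Static component of the hERG block
#'
#' Concentration response of the hERG binding strength:
#' \eqn{sbIKr = K_{max} C^h / (IC50h^h + C^h)}, bounded above by `Kmax`.
#'
#' @param C Drug concentration.
#' @param IC50h Half-effect concentration, `> 0`.
#' @param h Hill coefficient, `> 0`.
#' @param Kmax Maximum effect at saturating concentration, `>= 0`.
#' @return The dimensionless static binding strength.
#' @export
static_herg_block <- function(C, IC50h, h, Kmax) {
  if (any(IC50h <= 0)) stop("IC50h must be positive")
  if (any(h <= 0)) stop("Hill coefficient must be positive")
  if (any(Kmax < 0)) stop("Kmax must be non-negative")
  Kmax * C^h / (IC50h^h + C^h)
}

#' Scale a maximum conductance by a percent block
#'
#' @param g Maximum conductance (mS/uF).
#' @param b Percent block in `[0, 100]`.
#' @return `(100 - b)/100 * g`.
#' @export
scale_conductance <- function(g, b) {
  if (any(b < 0 | b > 100)) stop("percent block must be in [0, 100]")
  (100 - b) / 100 * g
}

.block_names <- c("bINa", "bINaL", "bIto", "bIKs", "bICaL", "bIK1",
                  "sbIKr", "Vhalf", "Ku")

#' Construct a drug-action block vector
#'
#' The nine model inputs: six percent current blocks, the static hERG
#' binding strength `sbIKr`, the trapping half-voltage `Vhalf` (mV) and the
#' unbinding rate `Ku` (1/ms).
#'
#' @param bINa,bINaL,bIto,bIKs,bICaL,bIK1 Percent block in `[0, 100]`.
#' @param sbIKr Static hERG binding strength, `>= 0`.
#' @param Vhalf Trapping half-voltage (mV).
#' @param Ku Unbinding rate (1/ms), `>= 0`.
#' @return Named numeric vector of class `block_vector`.
#' @export
block_vector <- function(bINa = 0, bINaL = 0, bIto = 0, bIKs = 0, bICaL = 0,
                         bIK1 = 0, sbIKr = 0, Vhalf = -100, Ku = 0) {
  v <- c(bINa = bINa, bINaL = bINaL, bIto = bIto, bIKs = bIKs,
         bICaL = bICaL, bIK1 = bIK1, sbIKr = sbIKr, Vhalf = Vhalf, Ku = Ku)
  if (any(v[1:6] < 0 | v[1:6] > 100))
    stop("percent blocks must be in [0, 100]")
  if (sbIKr < 0) stop("sbIKr must be non-negative")
  if (Ku < 0) stop("Ku must be non-negative")
  class(v) <- c("block_vector", "numeric")
  v
}

#' Translate a drug record into model inputs at a concentration multiple
#'
#' Applies the Hill block to each measured channel and the static hERG
#' concentration response at `C = multiple * EFTPC`; `Ku` and `Vhalf` are
#' copied from the record.  Channels without a measured IC50 are treated as
#' unblocked with a warning.
#'
#' @param drug One row of a drug table (list or single-row data.frame) with
#'   fields `EFTPC`, `IC50_<current>` / `h_<current>` for the six channels,
#'   and `Kmax`, `IC50h`, `h_herg`, `Ku`, `Vhalf`.
#' @param multiple Concentration as a multiple of EFTPC, `>= 0`.
#' @return A [block_vector()].
#' @export
drug_to_blocks <- function(drug, multiple = 1) {
  if (multiple < 0) stop("multiple must be non-negative")
  drug <- as.list(drug)
  C <- multiple * drug$EFTPC
  chans <- c("INa", "INaL", "Ito", "IKs", "ICaL", "IK1")
  blocks <- vapply(chans, function(ch) {
    ic <- drug[[paste0("IC50_", ch)]]
    hh <- drug[[paste0("h_", ch)]]
    if (is.null(ic) || is.na(ic)) {
      warning("no IC50 for ", ch, " in drug ", drug$name,
              "; treating as zero block")
      return(0)
    }
    hill_block(C, ic, hh)
  }, numeric(1))
  block_vector(bINa = blocks[["INa"]], bINaL = blocks[["INaL"]],
               bIto = blocks[["Ito"]], bIKs = blocks[["IKs"]],
               bICaL = blocks[["ICaL"]], bIK1 = blocks[["IK1"]],
               sbIKr = static_herg_block(C, drug$IC50h, drug$h_herg,
                                         drug$Kmax),
               Vhalf = drug$Vhalf, Ku = drug$Ku)
}

.drug_table_cols <- c("name", "EFTPC",
                      paste0("IC50_", c("INa", "INaL", "Ito", "IKs", "ICaL",
                                        "IK1")),
                      paste0("h_", c("INa", "INaL", "Ito", "IKs", "ICaL",
                                     "IK1")),
                      "Kmax", "IC50h", "h_herg", "Ku", "Vhalf",
                      "risk", "split")

#' Read a drug pharmacology table
#'
#' CSV with one compound per row.  Required columns: `name`, `EFTPC`,
#' `IC50_<current>` and `h_<current>` for the six non-hERG channels,
#' `Kmax`, `IC50h`, `h_herg`, `Ku`, `Vhalf`, `risk`
#' (high/intermediate/low) and `split` (training/validation).  All
#' concentrations (EFTPC and IC50s) must share one unit; the file declares
#' it in a `# unit:` comment line and no conversion is performed.
#'
#' @param path CSV file path.
#' @return data.frame of validated drug records.
#' @export
load_drug_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(.drug_table_cols, names(df))
  if (length(missing))
    stop("drug table missing column(s): ", paste(missing, collapse = ", "))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (!row$risk %in% c("high", "intermediate", "low"))
      stop("row ", i, ": unknown risk label '", row$risk, "'")
    ics <- unlist(row[grep("^IC50", names(row))])
    hs <- unlist(row[grep("^h_", names(row))])
    if (any(ics[!is.na(ics)] <= 0)) stop("row ", i, ": non-positive IC50")
    if (any(hs[!is.na(hs)] <= 0))
      stop("row ", i, ": non-positive Hill coefficient")
    if (!is.na(row$Kmax) && row$Kmax < 0) stop("row ", i, ": negative Kmax")
  }
  df
}

#' Write a drug pharmacology table
#' @param drugs data.frame as returned by [load_drug_table()].
#' @param path Output CSV path.
#' @param unit Concentration unit recorded in the header comment.
#' @export
write_drug_table <- function(drugs, path, unit = "nM") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# unit: ", unit), con)
  utils::write.csv(drugs, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The 28-drug CiPA reference metric table
#'
#' Per-drug mean metric values (averaged over 1-4x EFTPC): the EAD threshold
#' metric Th_EAD,hERG for the full nine-parameter drug action (`th_ead_c1`)
#' and for the sbIKr+bICaL-only ablation (`th_ead_c2`), `qnet` (nC/uF),
#' `apd90` (ms), `peakca` (nM), with the CiPA tertiary risk label and
#' training/validation split.  Compounds that never showed an EAD up to 100%
#' additional hERG block carry `NA` in the threshold column and `TRUE` in
#' the corresponding `noead_*` flag (a typed sentinel, never silently
#' coerced to a number).
#'
#' @return data.frame with 28 rows.
#' @export
table5 <- function() {
  path <- system.file("extdata", "cipa28_metrics.csv", package = "proarisk")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 28)
  for (col in c("th_ead_c1", "th_ead_c2")) {
    flag <- df[[col]] == "NoEAD"
    df[[sub("th_ead", "noead", col)]] <- flag
    df[[col]] <- suppressWarnings(as.numeric(ifelse(flag, NA, df[[col]])))
  }
  counts <- table(df$risk)
  stopifnot(counts[["high"]] == 8, counts[["intermediate"]] == 11,
            counts[["low"]] == 9,
            sum(df$split == "training") == 12,
            sum(df$split == "validation") == 16)
  df
}
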