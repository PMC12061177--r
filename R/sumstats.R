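#' GWAS summary statistics for one trait
#'
#' A `summary_stats` object holds per-SNP association records for a single
#' trait: one row per SNP with the effect allele, other allele, effect
#' estimate (log-odds scale for binary traits), its standard error, the
#' effect-allele frequency (may be missing), the association p-value and the
#' sample size. SNP identifiers are unique within an object.
#'
#' @param records data.frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `eaf`, `pval`, `n`.
#' @param trait_label character label for the trait.
#' @param provenance free-text source tag.
#' @param parse_report optional list describing how the records were parsed.
#' @return An object of class `summary_stats`.
#' @export
summary_stats <- function(records, trait_label, provenance = "",
                          parse_report = NULL) {
  required <- c("snp_id", "effect_allele", "other_allele", "beta", "se",
                "eaf", "pval", "n")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("records missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- as.data.frame(records)[, required]
  if (anyDuplicated(records$snp_id)) {
    stop("snp_id must be unique within a summary_stats object", call. = FALSE)
  }
  rownames(records) <- NULL
  structure(
    list(trait_label = trait_label, records = records,
         provenance = provenance, parse_report = parse_report),
    class = "summary_stats"
  )
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> %s: %d SNPs", x$trait_label,
              nrow(x$records)))
  if (nzchar(x$provenance)) cat(sprintf(" [%s]", x$provenance))
  cat("\n")
  if (!is.null(x$parse_report)) {
    pr <- x$parse_report
    cat(sprintf("  parsed: %d rows read, %d kept, %d dropped\n",
                pr$rows_read, pr$rows_kept, pr$rows_read - pr$rows_kept))
  }
  invisible(x)
}

#' @export
nsnp <- function(x) UseMethod("nsnp")

#' @export
nsnp.summary_stats <- function(x) nrow(x$records)

VALID_BASES <- c("A", "C", "G", "T")

# canonical field -> default file column name
default_column_map <- function() {
  c(snp_id = "snp_id", effect_allele = "effect_allele",
    other_allele = "other_allele", beta = "beta", se = "se",
    eaf = "eaf", pval = "pval", n = "n")
}

detect_delimiter <- function(header_line) {
  if (grepl("\t", header_line)) return("\t")
  if (grepl(",", header_line)) return(",")
  ""  # read.table default: any whitespace
}

parse_numeric_field <- function(x) {
  x <- trimws(x)
  x[x == "" | toupper(x) == "NA"] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a header-bearing delimited file (tab, comma or whitespace,
#' auto-detected unless `delim` is given), maps file columns to the canonical
#' fields via `column_map`, upper-cases alleles, validates every row against
#' the per-SNP invariants and drops invalid rows with a per-reason count.
#' Only `eaf` may be missing ("NA", case-insensitive, or empty).
#'
#' Drop reasons: `non_snp` (allele not a single A/C/G/T base, or identical
#' alleles), `nonpositive_se`, `bad_pval` (outside (0,1] or missing),
#' `bad_eaf` (present but outside (0,1)), `bad_beta` (missing or
#' non-numeric), `bad_n` (missing or < 1), `duplicate_id`.
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical field names
#'   (`snp_id`, `effect_allele`, `other_allele`, `beta`, `se`, `eaf`, `pval`,
#'   `n`) to the file's column names. Fields absent from the map use the
#'   canonical name itself.
#' @param trait_label label attached to the resulting object.
#' @param delim optional explicit delimiter (overrides auto-detection).
#' @param provenance free-text source tag (defaults to the file path).
#' @return A [summary_stats] object with a `parse_report` listing rows read,
#'   kept and dropped by reason.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_label = "trait",
                          delim = NULL, provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cmap <- default_column_map()
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(cmap))
    if (length(unknown) > 0) {
      stop("unknown canonical field(s) in column_map: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    cmap[names(column_map)] <- column_map
  }
  header_line <- readLines(path, n = 1L)
  if (length(header_line) == 0) stop("empty file: ", path, call. = FALSE)
  sep <- if (is.null(delim)) detect_delimiter(header_line) else delim
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  absent <- cmap[!(cmap %in% names(raw))]
  if (length(absent) > 0) {
    stop(sprintf("mandatory column(s) not found in %s: %s", path,
                 paste(sprintf("%s (for field %s)", absent, names(absent)),
                       collapse = ", ")), call. = FALSE)
  }
  df <- data.frame(
    snp_id = trimws(raw[[cmap["snp_id"]]]),
    effect_allele = toupper(trimws(raw[[cmap["effect_allele"]]])),
    other_allele = toupper(trimws(raw[[cmap["other_allele"]]])),
    beta = parse_numeric_field(raw[[cmap["beta"]]]),
    se = parse_numeric_field(raw[[cmap["se"]]]),
    eaf = parse_numeric_field(raw[[cmap["eaf"]]]),
    pval = parse_numeric_field(raw[[cmap["pval"]]]),
    n = parse_numeric_field(raw[[cmap["n"]]]),
    stringsAsFactors = FALSE
  )
  rows_read <- nrow(df)
  drop_reason <- rep(NA_character_, rows_read)
  flag <- function(bad, reason) {
    bad[is.na(bad)] <- TRUE
    drop_reason[is.na(drop_reason) & bad] <<- reason
  }
  flag(!(df$effect_allele %in% VALID_BASES) |
         !(df$other_allele %in% VALID_BASES) |
         df$effect_allele == df$other_allele, "non_snp")
  flag(is.na(df$beta), "bad_beta")
  flag(is.na(df$se) | df$se <= 0, "nonpositive_se")
  flag(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "bad_pval")
  flag(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "bad_eaf")
  flag(is.na(df$n) | df$n < 1, "bad_n")
  dup <- duplicated(df$snp_id)
  flag(dup, "duplicate_id")
  kept <- df[is.na(drop_reason), , drop = FALSE]
  if (nrow(kept) == 0) {
    stop(sprintf("no valid summary-statistic rows in %s (%d read)", path,
                 rows_read), call. = FALSE)
  }
  kept$n <- as.integer(round(kept$n))
  reasons <- table(drop_reason[!is.na(drop_reason)])
  report <- list(
    rows_read = rows_read,
    rows_kept = nrow(kept),
    dropped = as.list(stats::setNames(as.integer(reasons), names(reasons)))
  )
  summary_stats(kept, trait_label = trait_label, provenance = provenance,
                parse_report = report)
}

#' Write a flat table of records as tab-delimited text
#'
#' Writes a data.frame with a header row, tab delimiters and "NA" for missing
#' values. Numeric fields are serialized with enough significant digits that
#' a write/read round-trip preserves strings and integers exactly and reals
#' to at least 12 significant digits.
#'
#' @param rows data.frame (all records share a field set).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- out[[j]]
      s <- sprintf("%.15g", v)
      s[is.na(v)] <- NA_character_
      out[[j]] <- s
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("cannot write table to ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}

#' Write a summary_stats object to a tab-delimited file
#'
#' @param ss a [summary_stats] object.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_sumstats <- function(ss, path) {
  stopifnot(inherits(ss, "summary_stats"))
  write_table(ss$records, path)
}
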