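#' @keywords internal
"_PACKAGE"

# Required column order of the on-disk sample schema.
DATASET_COLUMNS <- c("taxon_id", "taxon_name", "tax_class",
                     "d13C", "d15N", "pctC", "pctN")

VALID_CLASSES <- c("Actinopterygii", "Chondrichthyes", "Cephalopoda",
                   "Decapoda", "Gasteropoda", "Polychaeta", "Bivalvia",
                   "Baseline")

#' Construct a community isotope dataset
#'
#' A community dataset holds one row per analysed individual, with the
#' taxon label, taxonomic class, both tracers (d13C in permil vs VPDB,
#' d15N in permil vs atmospheric N2) and elemental content. The C/N mass
#' ratio, a proxy for lipid content, is derived from `pctC`/`pctN` when
#' both are present.
#'
#' @param df data.frame with columns `taxon_id`, `taxon_name`, `tax_class`,
#'   `d13C`, `d15N` and optionally `pctC`, `pctN`.
#' @return A data.frame of class `community_dataset` with a derived
#'   `cn_ratio` column.
#' @export
community_dataset <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(c("taxon_id", "taxon_name", "tax_class", "d13C", "d15N"),
                          names(df))
  if (length(missing_cols) > 0) {
    stop("dataset schema error: missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"pctC" %in% names(df)) df$pctC <- NA_real_
  if (!"pctN" %in% names(df)) df$pctN <- NA_real_
  for (col in c("d13C", "d15N", "pctC", "pctN")) {
    if (!is.numeric(df[[col]])) {
      num <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(num) & !is.na(df[[col]]))
      if (length(bad) > 0) {
        stop("parse error: non-numeric value in column '", col, "' at row ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      df[[col]] <- num
    }
  }
  df <- df[, c("taxon_id", "taxon_name", "tax_class", "d13C", "d15N", "pctC", "pctN")]
  df$taxon_id <- as.character(df$taxon_id)
  df$taxon_name <- as.character(df$taxon_name)
  df$tax_class <- as.character(df$tax_class)
  df$cn_ratio <- ifelse(!is.na(df$pctC) & !is.na(df$pctN) & df$pctN > 0,
                        df$pctC / df$pctN, NA_real_)
  rownames(df) <- NULL
  class(df) <- c("community_dataset", "data.frame")
  df
}

#' Read per-individual isotope samples from CSV
#'
#' Expects the schema `taxon_id,taxon_name,tax_class,d13C,d15N,pctC,pctN`
#' (header required, decimal point, UTF-8). Row order is preserved.
#'
#' @param path path to a CSV file.
#' @return a [community_dataset()].
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing_cols <- setdiff(DATASET_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("dataset schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("d13C", "d15N", "pctC", "pctN")) {
    val <- raw[[col]]
    if (!is.numeric(val)) {
      num <- suppressWarnings(as.numeric(val))
      bad <- which(is.na(num) & !is.na(val) & val != "" & val != "NA")
      if (length(bad) > 0) {
        stop("parse error: non-numeric value in column '", col,
             "' at row ", paste(bad, collapse = ", "), call. = FALSE)
      }
      raw[[col]] <- num
    }
  }
  community_dataset(raw)
}

#' Write a community dataset to CSV
#'
#' Emits exactly the schema accepted by [read_samples()]; the derived
#' `cn_ratio` column is not written.
#'
#' @param dataset a [community_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(dataset, path) {
  stopifnot(inherits(dataset, "community_dataset"))
  utils::write.csv(as.data.frame(dataset)[, DATASET_COLUMNS], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Screen a dataset for quality flags
#'
#' Reports (never corrects) rows needing attention: a C/N ratio at or above
#' `cn_max` signals lipid content that would bias d13C (the conventional
#' screen is C/N < 4 for untreated tissue), and tracer values outside
#' plausible marine ranges (d13C in \[-40, 0\], d15N in \[0, 30\]) signal
#' unit or transcription problems. Rows lacking %C or %N are skipped by the
#' lipid screen. The input is never modified.
#'
#' @param dataset a [community_dataset()].
#' @param cn_max lipid-screen threshold on the C/N mass ratio (default 4).
#' @return data.frame with columns `row`, `taxon_id`, `flag`, `message`;
#'   zero rows when the dataset is clean.
#' @export
validate_samples <- function(dataset, cn_max = 4) {
  stopifnot(inherits(dataset, "community_dataset"), nrow(dataset) > 0)
  flags <- list()
  add <- function(rows, flag, msg) {
    if (length(rows) > 0) {
      flags[[length(flags) + 1]] <<- data.frame(
        row = rows, taxon_id = dataset$taxon_id[rows],
        flag = flag, message = msg, stringsAsFactors = FALSE)
    }
  }
  add(which(!is.na(dataset$cn_ratio) & dataset$cn_ratio >= cn_max),
      "lipid", sprintf("C/N ratio >= %g; lipid correction may be required", cn_max))
  add(which(dataset$d13C < -40 | dataset$d13C > 0),
      "d13C_range", "d13C outside [-40, 0] permil")
  add(which(dataset$d15N < 0 | dataset$d15N > 30),
      "d15N_range", "d15N outside [0, 30] permil")
  add(which(!is.na(dataset$pctC) & dataset$pctC <= 0), "pctC", "%C must be > 0")
  add(which(!is.na(dataset$pctN) & dataset$pctN <= 0), "pctN", "%N must be > 0")
  if (length(flags) == 0) {
    return(data.frame(row = integer(), taxon_id = character(),
                      flag = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, flags)
  out[order(out$row), , drop = FALSE]
}

#' Per-taxon summary statistics
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of both
#' tracers for every taxon. Single-individual taxa are reported with SD 0
#' and a warning, since no dispersion estimate exists.
#'
#' @param dataset a [community_dataset()].
#' @return data.frame with one row per taxon (first-appearance order):
#'   `taxon_id`, `taxon_name`, `tax_class`, `n`, `mean_d13C`, `sd_d13C`,
#'   `mean_d15N`, `sd_d15N`.
#' @export
summarize_taxa <- function(dataset) {
  stopifnot(inherits(dataset, "community_dataset"), nrow(dataset) > 0)
  ids <- unique(dataset$taxon_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    rows <- dataset[dataset$taxon_id == id, ]
    n <- nrow(rows)
    data.frame(taxon_id = id,
               taxon_name = rows$taxon_name[1],
               tax_class = rows$tax_class[1],
               n = n,
               mean_d13C = mean(rows$d13C),
               sd_d13C = if (n > 1) stats::sd(rows$d13C) else 0,
               mean_d15N = mean(rows$d15N),
               sd_d15N = if (n > 1) stats::sd(rows$d15N) else 0,
               stringsAsFactors = FALSE)
  }))
  if (any(out$n == 1)) {
    warning("taxa with n = 1 reported with SD = 0: ",
            paste(out$taxon_id[out$n == 1], collapse = ", "), call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Pool summary moments across groups
#'
#' Standard pooled-moments combination: the pooled mean is the n-weighted
#' mean, and the pooled variance combines within-group variance and
#' between-group mean dispersion,
#' `var = sum(n_i (sd_i^2 + mean_i^2)) / N - pooled_mean^2`.
#' Population (n denominator) moments are used inside the formula, which
#' agrees with pooling the raw observations exactly when the input SDs are
#' population SDs; with sample SDs the discrepancy is O(1/n) and immaterial
#' at the reported precision.
#'
#' @param means,sds,ns numeric vectors of equal length (per-group moments).
#' @return named numeric vector `c(mean, sd, n)`.
#' @export
pool_moments <- function(means, sds, ns) {
  stopifnot(length(means) == length(sds), length(means) == length(ns),
            all(ns >= 1), all(sds >= 0))
  n_tot <- sum(ns)
  m <- sum(ns * means) / n_tot
  v <- sum(ns * (sds^2 + means^2)) / n_tot - m^2
  c(mean = m, sd = sqrt(max(v, 0)), n = n_tot)
}

#' Pool member taxa into one group summary
#'
#' With raw rows available, the group mean/SD are computed over the pooled
#' individuals directly. The summary-only path, [pool_moments()], is used by
#' source pooling when no raw rows exist.
#'
#' @param dataset a [community_dataset()].
#' @param member_taxa character vector of `taxon_id`s to pool.
#' @param group_id label for the pooled group.
#' @return one-row data.frame: `group_id`, `member_taxa` (comma-joined),
#'   `n_total`, `mean_d13C`, `sd_d13C`, `mean_d15N`, `sd_d15N`.
#' @export
pool_group <- function(dataset, member_taxa, group_id = "group") {
  stopifnot(inherits(dataset, "community_dataset"))
  unknown <- setdiff(member_taxa, unique(dataset$taxon_id))
  if (length(unknown) > 0) {
    stop("unknown member taxon: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  rows <- dataset[dataset$taxon_id %in% member_taxa, ]
  data.frame(group_id = group_id,
             member_taxa = paste(member_taxa, collapse = ","),
             n_total = nrow(rows),
             mean_d13C = mean(rows$d13C),
             sd_d13C = stats::sd(rows$d13C),
             mean_d15N = mean(rows$d15N),
             sd_d15N = stats::sd(rows$d15N),
             stringsAsFactors = FALSE)
}
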