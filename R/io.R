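#' Read a probe table
#'
#' Reads a tab-delimited probe table into a tidy tibble. Two dialects:
#' \describe{
#'   \item{`tsv`}{columns `probe_id`, optionally `probe_type`
#'     (`regular`/`negative`), one or more `intensity*` columns and optional
#'     matching `detection_pval*` columns.}
#'   \item{`illumina-profile`}{Sample-Probe-Profile-style export: a
#'     `ProbeID`/`PROBE_ID` column, `AVG_Signal` columns (one per array) and
#'     optional `Detection Pval` columns; column names are normalized to the
#'     tsv dialect.}
#' }
#' Negative probes are identified by the `probe_type` column or, failing
#' that, by a `negatives` file listing negative probe IDs (one per line).
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"illumina-profile"`.
#' @param negatives Optional path to a file of negative probe IDs.
#' @return A tibble with columns `probe_id`, `probe_type`, `intensity_*` and
#'   optionally `detection_pval_*`.
#' @export
read_probe_table <- function(path, dialect = c("tsv", "illumina-profile"),
                             negatives = NULL) {
  dialect <- match.arg(dialect)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (nrow(tbl) == 0L || ncol(tbl) < 2L) {
    abort("empty or headerless probe table.", class = "gammabg_format_error")
  }
  if (dialect == "illumina-profile") {
    nm <- names(tbl)
    id_col <- grep("^probe[._ ]?id$", nm, ignore.case = TRUE, value = TRUE)
    sig_col <- grep("avg[._ ]?signal", nm, ignore.case = TRUE, value = TRUE)
    pv_col <- grep("detection([._ ]?pval)?", nm, ignore.case = TRUE, value = TRUE)
    if (length(id_col) != 1L || length(sig_col) < 1L) {
      abort("illumina-profile dialect needs a ProbeID and AVG_Signal column(s).",
            class = "gammabg_format_error")
    }
    ren <- setNames(nm, nm)
    ren[id_col] <- "probe_id"
    ren[sig_col] <- if (length(sig_col) == 1L) "intensity" else
      sprintf("intensity_%d", seq_along(sig_col))
    ren[pv_col] <- if (length(pv_col) == 1L) "detection_pval" else
      sprintf("detection_pval_%d", seq_along(pv_col))
    names(tbl) <- unname(ren)
  }
  if (!"probe_id" %in% names(tbl)) {
    abort("column `probe_id` is required.", class = "gammabg_format_error")
  }
  tbl$probe_id <- as.character(tbl$probe_id)
  dup <- tbl$probe_id[duplicated(tbl$probe_id)]
  if (length(dup)) {
    abort(sprintf("duplicate probe_id(s): %s", paste(head(dup, 3), collapse = ", ")),
          class = "gammabg_format_error")
  }
  int_cols <- grep("^intensity", names(tbl), value = TRUE)
  if (length(int_cols) == 0L) {
    abort("at least one intensity column is required.",
          class = "gammabg_format_error")
  }
  for (cc in int_cols) {
    if (!is.numeric(tbl[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tbl[[cc]]))))[1]
      abort(sprintf("non-numeric intensity in column `%s`, row %d.", cc, bad),
            class = "gammabg_format_error")
    }
  }
  for (cc in grep("^detection_pval", names(tbl), value = TRUE)) {
    v <- tbl[[cc]]
    if (!is.numeric(v) || any(v < 0 | v > 1, na.rm = TRUE)) {
      abort(sprintf("column `%s` must contain p-values in [0, 1].", cc),
            class = "gammabg_format_error")
    }
  }
  if (!"probe_type" %in% names(tbl)) {
    if (!is.null(negatives)) {
      neg_ids <- readr::read_lines(negatives)
      tbl$probe_type <- ifelse(tbl$probe_id %in% neg_ids, "negative", "regular")
    } else {
      tbl$probe_type <- "regular"
    }
  }
  bad_type <- setdiff(unique(tbl$probe_type), c("regular", "negative"))
  if (length(bad_type)) {
    abort(sprintf("unknown probe_type value(s): %s",
                  paste(bad_type, collapse = ", ")),
          class = "gammabg_format_error")
  }
  tbl
}

#' Write a probe table
#'
#' Tab-delimited, UTF-8, `.` decimal; value round-trips with
#' [read_probe_table()] are bit-exact.
#'
#' @param tbl A probe-table tibble.
#' @param path Output path.
#' @return `tbl`, invisibly.
#' @export
write_probe_table <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(tbl)
}

#' Run a background-correction pipeline from a configuration
#'
#' Orchestrates the per-array pipeline: read a probe table, obtain negative
#' probes (directly, or inferred from detection p-values when the table
#' carries no negatives), fit the requested model on each intensity column
#' independently (arrays never share parameters), correct, and optionally
#' write the corrected table plus a JSON sidecar of fits. One log line per
#' array reports the estimates, log-likelihood and convergence.
#'
#' @param config A named list (or path to a JSON file) with keys:
#'   `input` (path), `method` (`"normal-gamma"`, `"normexp-mle"`,
#'   `"normexp-rma"`, `"normexp-np"`, `"subtract"`), and optionally
#'   `dialect`, `negatives` (path), `n_neg` (negatives to infer; default
#'   1000), `output` (TSV path), `quiet`.
#' @return A list with `table` (corrected tibble: intensity columns replaced
#'   by `signal_hat_*` columns) and `fits` (per-array `"bg_fit"` or `NULL` for
#'   subtraction).
#' @export
run_correct <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$input) || is.null(config$method)) {
    abort("config must name `input` and `method`.",
          class = "gammabg_config_error")
  }
  method <- match.arg(config$method,
                      c("normal-gamma", "normexp-mle", "normexp-rma",
                        "normexp-np", "subtract"))
  tbl <- read_probe_table(config$input,
                          dialect = config$dialect %||% "tsv",
                          negatives = config$negatives)
  int_cols <- grep("^intensity", names(tbl), value = TRUE)
  has_neg <- any(tbl$probe_type == "negative")
  needs_neg <- method != "normexp-rma"
  quiet <- isTRUE(config$quiet)
  out <- tbl
  fits <- list()
  for (cc in int_cols) {
    x <- tbl[[cc]]
    reg <- x[tbl$probe_type == "regular"]
    if (has_neg) {
      neg <- x[tbl$probe_type == "negative"]
    } else if (needs_neg) {
      pv_col <- sub("^intensity", "detection_pval", cc)
      if (!pv_col %in% names(tbl)) {
        abort(paste("no negative probes and no detection p-values: supply a",
                    "`negatives` file or detection p-value columns to invert."),
              class = "gammabg_config_error")
      }
      neg <- infer_negatives(tbl[[pv_col]][tbl$probe_type == "regular"], reg,
                             n_neg = config$n_neg %||% 1000)
    } else {
      neg <- numeric()
    }
    d <- array_data(regular = reg, negative = neg)
    t0 <- proc.time()[3]
    if (method == "subtract") {
      sig <- bg_correct_subtract(x, neg)
      fits[[cc]] <- NULL
      if (!quiet) message(sprintf("[%s] subtract: median(neg) = %g (%.2fs)",
                                  cc, median(neg), proc.time()[3] - t0))
    } else {
      fit <- fit_background(d, model = method)
      sig <- if (method == "normal-gamma") {
        bg_correct_normgamma(x, fit$params)
      } else {
        bg_correct_normexp(x, fit$params)
      }
      fits[[cc]] <- fit
      if (!quiet) {
        e <- unlist(unclass(fit$params))
        message(sprintf("[%s] %s: %s | loglik %.2f | %s (%.2fs)",
                        cc, fit$method,
                        paste(sprintf("%s=%.4g", names(e), e), collapse = " "),
                        fit$loglik,
                        if (fit$converged) "converged" else "NOT converged",
                        proc.time()[3] - t0))
      }
    }
    out[[sub("^intensity", "signal_hat", cc)]] <- sig
    out[[cc]] <- NULL
  }
  if (!is.null(config$output)) {
    write_probe_table(out, config$output)
    sidecar <- sub("\\.tsv$", "", config$output)
    fit_info <- lapply(fits, function(f) {
      if (is.null(f)) return(NULL)
      c(as.list(unlist(unclass(f$params))),
        list(loglik = f$loglik, converged = f$converged, method = f$method))
    })
    jsonlite::write_json(
      list(method = method, config = config[setdiff(names(config), "quiet")],
           fits = fit_info),
      paste0(sidecar, ".fits.json"), auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  list(table = out, fits = fits)
}
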