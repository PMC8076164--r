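# Per-collection morphometric summaries for Hebeloma spores and
# cheilocystidia, following the standard measurement protocol: at least 50
# spores per collection measured in Melzer's reagent (length, width, Q =
# length/width), and cheilocystidia measured as length x apex (A) x
# narrowest central width (M) x maximum lower-half width (B), with the
# ratios A/M, A/B and B/M computed per cystidium and then averaged.

#' Summarise spore measurements for one collection
#'
#' Computes the per-collection spore summary used throughout Hebeloma
#' taxonomy: mean, median, sample standard deviation and 5/95 percentiles of
#' length, width and the shape index Q (length/width). Q is computed per
#' spore and then summarised (mean of ratios), so `mean_q` is generally not
#' `mean_length / mean_width`.
#'
#' The measurement protocol asks for at least 50 spores per collection;
#' smaller samples are summarised all the same but flagged with a
#' `protocol_warning`.
#'
#' @param length,width Numeric vectors of spore maximum length and width in
#'   micrometres (apiculus excluded). Must be positive and of equal length.
#' @param quantile_type Quantile estimator passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).
#' @param min_n Protocol sample size below which a warning flag is set
#'   (default 50).
#' @return An object of class `spore_summary`: a list with `n`, means,
#'   medians, sample SDs and 5%/95% percentiles of length, width and Q, and
#'   a logical `protocol_warning`.
#' @examples
#' s <- summarize_spores(length = c(10, 11, 12, 13), width = c(5, 6, 5, 6))
#' s$mean_length  # 11.5
#' s$mean_q       # mean of per-spore ratios, 2.1
#' @export
summarize_spores <- function(length, width, quantile_type = 7, min_n = 50) {
  if (length(length) == 0L || length(width) == 0L)
    stop("no measurements")
  if (length(length) != length(width))
    stop("length and width vectors differ in length")
  if (anyNA(length) || anyNA(width) || any(length <= 0) || any(width <= 0))
    stop("invalid measurement: all spore lengths and widths must be positive")
  q <- length / width
  summ <- function(x) {
    p <- stats::quantile(x, c(0.05, 0.5, 0.95), type = quantile_type,
                         names = FALSE)
    list(mean = mean(x), median = p[2], sd = stats::sd(x),
         p5 = p[1], p95 = p[3])
  }
  l <- summ(length); w <- summ(width); qq <- summ(q)
  out <- list(
    n = length(length),
    mean_length = l$mean, median_length = l$median, sd_length = l$sd,
    p5_length = l$p5, p95_length = l$p95,
    mean_width = w$mean, median_width = w$median, sd_width = w$sd,
    p5_width = w$p5, p95_width = w$p95,
    mean_q = qq$mean, median_q = qq$median, sd_q = qq$sd,
    p5_q = qq$p5, p95_q = qq$p95,
    protocol_warning = length(length) < min_n
  )
  class(out) <- "spore_summary"
  out
}

#' @export
print.spore_summary <- function(x, ...) {
  cat(sprintf("Spore summary (n = %d%s)\n", x$n,
              if (x$protocol_warning) ", below-protocol sample" else ""))
  cat(sprintf("  size : %.1f x %.1f um (median %.1f x %.1f)\n",
              x$mean_length, x$mean_width, x$median_length, x$median_width))
  cat(sprintf("  5-95%%: %.1f-%.1f x %.1f-%.1f um\n",
              x$p5_length, x$p95_length, x$p5_width, x$p95_width))
  cat(sprintf("  Q    : mean %.2f, median %.2f, 5-95%% %.2f-%.2f\n",
              x$mean_q, x$median_q, x$p5_q, x$p95_q))
  invisible(x)
}

#' Summarise cheilocystidium measurements for one collection
#'
#' Full measurements are length x apex width (A) x narrowest central width
#' (M) x maximum lower-half width (B); the ratios A/M, A/B and B/M are
#' formed per cystidium and averaged (mean of ratios). The protocol measures
#' about 100 apex widths along the lamella edge and at least 20 full
#' quadruples; shortfalls set warning flags rather than failing.
#'
#' The ratio of the mean widths (`ratio_of_means_*`) is also reported as a
#' diagnostic, because it can fall outside the range of the per-cystidium
#' ratios and must not be substituted for them.
#'
#' @param length,apex,middle,base Numeric vectors (micrometres), one entry
#'   per fully measured cystidium; all positive, equal lengths.
#' @param apex_widths Optional numeric vector of apex widths from the
#'   lamella-edge survey (may be empty; then apex statistics come from the
#'   full measurements only).
#' @param min_full,min_apex Protocol sizes triggering warning flags
#'   (defaults 20 and 100).
#' @return An object of class `cystidia_summary` with counts, mean
#'   dimensions, mean per-cystidium ratios, ratio-of-means diagnostics and
#'   warning flags.
#' @examples
#' cs <- summarize_cheilocystidia(length = c(40, 60), apex = c(8, 6),
#'                                middle = c(4, 4), base = c(4, 8))
#' cs$mean_ratio_am  # (2.0 + 1.5) / 2 = 1.75
#' @export
summarize_cheilocystidia <- function(length, apex, middle, base,
                                     apex_widths = numeric(),
                                     min_full = 20, min_apex = 100) {
  n <- length(length)
  if (n == 0L) stop("no measurements")
  if (length(apex) != n || length(middle) != n || length(base) != n)
    stop("length, apex, middle and base vectors must have equal length")
  vals <- c(length, apex, middle, base, apex_widths)
  if (anyNA(vals) || any(vals <= 0))
    stop("invalid measurement: all cystidium measurements must be positive")
  apex_all <- c(apex, apex_widths)
  out <- list(
    n_full = n,
    n_apex_only = length(apex_widths),
    mean_length = mean(length),
    mean_a = mean(apex_all),
    mean_m = mean(middle),
    mean_b = mean(base),
    mean_ratio_am = mean(apex / middle),
    mean_ratio_ab = mean(apex / base),
    mean_ratio_bm = mean(base / middle),
    ratio_of_means_am = mean(apex) / mean(middle),
    ratio_of_means_ab = mean(apex) / mean(base),
    ratio_of_means_bm = mean(base) / mean(middle),
    protocol_warning_full = n < min_full,
    protocol_warning_apex = length(apex_all) < min_apex
  )
  class(out) <- "cystidia_summary"
  out
}

#' @export
print.cystidia_summary <- function(x, ...) {
  cat(sprintf("Cheilocystidia summary (n full = %d, apex-only = %d)\n",
              x$n_full, x$n_apex_only))
  cat(sprintf("  mean %.1f x %.1f (A) x %.1f (M) x %.1f (B) um\n",
              x$mean_length, x$mean_a, x$mean_m, x$mean_b))
  cat(sprintf("  ratios A/M %.2f, A/B %.2f, B/M %.2f (means of ratios)\n",
              x$mean_ratio_am, x$mean_ratio_ab, x$mean_ratio_bm))
  invisible(x)
}

# ---- Ordinal spore-trait codes (O/P/D scales) -------------------------------

.opd_alphabets <- list(
  O = paste0("O", 0:4),   # ornamentation
  P = paste0("P", 0:3),   # loosening of the perispore
  D = paste0("D", 0:4)    # dextrinoidity in Melzer's reagent
)

#' Parse an ordinal spore-trait code string
#'
#' Species descriptions record ornamentation, perispore loosening and
#' dextrinoidity as concatenated class tokens on the O0-O4, P0-P3 and D0-D4
#' scales, with parentheses marking rare states, e.g. `"O1O2 (O3)"` or
#' `"(D2) D3 (D4)"`. The parser returns the class set with a parenthetical
#' flag per class; order and whitespace are ignored.
#'
#' @param code A single code string.
#' @return A data frame of class `opd_codes` with columns `class` and
#'   `parenthetical`, plus attributes `scale` ("O", "P" or "D") and `code`
#'   (the input).
#' @examples
#' parse_opd("(D2) D3 (D4)")
#' @export
parse_opd <- function(code) {
  if (length(code) != 1L || is.na(code) || !nzchar(trimws(code)))
    stop("no measurements/classes: empty O/P/D code string")
  s <- trimws(code)
  toks <- gregexpr("\\(\\s*[OPDopd]\\d\\s*\\)|[OPDopd]\\d", s)[[1]]
  if (toks[1] == -1L) stop("unknown token in O/P/D code: ", sQuote(s))
  pieces <- regmatches(s, gregexpr("\\(\\s*[OPDopd]\\d\\s*\\)|[OPDopd]\\d", s))[[1]]
  # anything left over after removing recognised tokens is an unknown token
  rest <- gsub("\\(\\s*[OPDopd]\\d\\s*\\)|[OPDopd]\\d|\\s", "", s)
  if (nzchar(rest))
    stop("unknown token in O/P/D code: ", sQuote(rest))
  paren <- grepl("^\\(", pieces)
  cls <- toupper(gsub("[() ]", "", pieces))
  scale <- unique(substr(cls, 1, 1))
  if (length(scale) != 1L)
    stop("mixed scales in O/P/D code: ", sQuote(s))
  bad <- setdiff(cls, .opd_alphabets[[scale]])
  if (length(bad))
    stop("unknown token in O/P/D code: ", paste(sQuote(bad), collapse = ", "))
  keep <- !duplicated(cls)
  out <- data.frame(class = cls[keep],
                    parenthetical = paren[keep] & !(cls[keep] %in% cls[!paren]),
                    stringsAsFactors = FALSE)
  attr(out, "scale") <- scale
  attr(out, "code") <- s
  class(out) <- c("opd_codes", "data.frame")
  out
}

#' Test for a class in an ordinal code set
#'
#' `opd_has()` tests mere presence; `opd_many()` tests presence as a common
#' (non-parenthetical) state, the reading used by key leads phrased
#' "many spores X".
#'
#' @param codes An `opd_codes` object from [parse_opd()].
#' @param class A class token such as `"D3"`.
#' @return Logical scalar.
#' @export
opd_has <- function(codes, class) class %in% codes$class

#' @rdname opd_has
#' @export
opd_many <- function(codes, class) {
  i <- match(class, codes$class)
  !is.na(i) && !codes$parenthetical[i]
}

#' @export
format.opd_codes <- function(x, ...) {
  paste(ifelse(x$parenthetical, paste0("(", x$class, ")"), x$class),
        collapse = " ")
}

#' @export
print.opd_codes <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# ---- Measurement file I/O ---------------------------------------------------

#' Read raw measurement tables
#'
#' Spore files have one row per spore with columns `length,width`;
#' cystidium files one row per cystidium with `length,apex,middle,base`;
#' apex-width files a single column `apex`. Comma- and tab-separated files
#' (with a header) are both accepted.
#'
#' @param path Path to a delimited text file.
#' @return A data frame of measurements.
#' @export
read_spore_measurements <- function(path) {
  d <- .read_delim_auto(path)
  need <- c("length", "width")
  if (!all(need %in% names(d)))
    stop("spore measurement file must have columns: length, width")
  d[need]
}

#' @rdname read_spore_measurements
#' @export
read_cystidia_measurements <- function(path) {
  d <- .read_delim_auto(path)
  need <- c("length", "apex", "middle", "base")
  if (!all(need %in% names(d)))
    stop("cystidium measurement file must have columns: length, apex, middle, base")
  d[need]
}

#' @rdname read_spore_measurements
#' @export
read_apex_widths <- function(path) {
  d <- .read_delim_auto(path)
  if (!"apex" %in% names(d))
    stop("apex-width file must have a column: apex")
  d$apex
}

.read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, strip.white = TRUE,
                    stringsAsFactors = FALSE)
}

#' Flatten summaries to a one-row data frame
#'
#' Used when exporting one CSV row per collection.
#'
#' @param x A `spore_summary` or `cystidia_summary`.
#' @param ... Unused.
#' @return A one-row data frame.
#' @export
as.data.frame.spore_summary <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' @export
as.data.frame.cystidia_summary <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}
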