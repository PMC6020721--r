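#' Construct a QSM specification
#'
#' A Quality Sequencing Minimum (QSM) declares the minimum quality a
#' laboratory requires of its sequencing data in three metrics: depth of
#' coverage (C), base quality (B) and mapping quality (M). Written
#' `CX_BY(P_Y)_MZ(P_Z)`, it requires every base of a test region to be
#' covered by at least `X` reads, with a Phred base quality of at least `Y`
#' in at least `P_Y` percent of reads and a Phred mapping quality of at
#' least `Z` in at least `P_Z` percent of reads. An optional tool chain
#' records the software (name and version) that produced the reads,
#' qualities and calls, and an optional exception list names regions
#' excluded from the claim on a report.
#'
#' Phred thresholds above 93 are rejected (93 is the highest score encodable
#' in Sanger FASTQ) and thresholds above 60 draw a warning, since no current
#' base caller or mapper emits them -- both guards exist to catch typos.
#' Percentages may be fractional (e.g. 97.5).
#'
#' @param X Minimum depth of coverage (reads per base), non-negative integer.
#' @param Y Minimum Phred base quality, non-negative integer.
#' @param P_Y Minimum percent of reads whose base call reaches `Y`, in
#'   `[0, 100]`.
#' @param Z Minimum Phred mapping quality, non-negative integer.
#' @param P_Z Minimum percent of reads whose mapping quality reaches `Z`, in
#'   `[0, 100]`.
#' @param toolchain Tool chain as a data frame with columns `name` and
#'   `version`, a list of `c(name, version)` pairs, or `NULL`.
#' @param exceptions Character vector of human-readable region labels
#'   excluded from the QSM claim (possibly empty).
#' @return An object of class `qsm_spec`.
#' @examples
#' qsm_spec(50, 10, 85, 20, 95)
#' parse_qsm("C50_B10(85)_M20(95)")
#' @seealso [parse_qsm()], [render_qsm()]
#' @export
qsm_spec <- function(X, Y, P_Y, Z, P_Z, toolchain = NULL,
                     exceptions = character()) {
  check_count <- function(v, what) {
    if (length(v) != 1L || is.na(v) || !is.numeric(v) || v < 0 ||
        v != trunc(v))
      stop(what, " threshold must be a single non-negative integer, got ",
           deparse(v), call. = FALSE)
    as.integer(v)
  }
  check_pct <- function(v, what) {
    if (length(v) != 1L || is.na(v) || !is.numeric(v) || v < 0 || v > 100)
      stop(what, " percentage must be a single value in [0, 100], got ",
           deparse(v), call. = FALSE)
    as.numeric(v)
  }
  X <- check_count(X, "C (depth)")
  Y <- check_count(Y, "B (base quality)")
  Z <- check_count(Z, "M (mapping quality)")
  for (ph in c(B = Y, M = Z)) {
    if (ph > 93L)
      stop("Phred threshold ", ph, " exceeds 93, the maximum encodable ",
           "score; likely a typo", call. = FALSE)
  }
  if (Y > 60L || Z > 60L)
    warning("Phred threshold above 60: no current tool emits such scores",
            call. = FALSE)
  P_Y <- check_pct(P_Y, "B")
  P_Z <- check_pct(P_Z, "M")
  structure(
    list(X = X, Y = Y, P_Y = P_Y, Z = Z, P_Z = P_Z,
         toolchain = as_toolchain(toolchain),
         exceptions = as.character(exceptions)),
    class = "qsm_spec")
}

as_toolchain <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L) || length(x) == 0L)
    return(data.frame(name = character(), version = character(),
                      stringsAsFactors = FALSE))
  if (is.data.frame(x)) {
    stopifnot(all(c("name", "version") %in% names(x)))
    return(data.frame(name = as.character(x$name),
                      version = as.character(x$version),
                      stringsAsFactors = FALSE))
  }
  if (is.list(x)) {
    bad <- !vapply(x, function(e) is.character(e) && length(e) == 2L,
                   logical(1))
    if (any(bad))
      stop("toolchain entries must be c(name, version) character pairs",
           call. = FALSE)
    return(data.frame(name = vapply(x, `[`, "", 1L),
                      version = vapply(x, `[`, "", 2L),
                      stringsAsFactors = FALSE))
  }
  stop("toolchain must be NULL, a list of pairs, or a data frame",
       call. = FALSE)
}

#' @export
print.qsm_spec <- function(x, ...) {
  cat("QSM:", render_qsm(x, style = "short"), "\n")
  if (nrow(x$toolchain))
    cat("tool chain:",
        paste0(x$toolchain$name, " ", x$toolchain$version, collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
format.qsm_spec <- function(x, ...) {
  render_qsm(x, style = if (nrow(x$toolchain)) "full" else "short")
}

# Format a percentage without trailing zeros ("85", "97.5").
fmt_pct <- function(p) {
  s <- format(p, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  s
}

#' Parse a QSM string
#'
#' Parses the standardised QSM format `CX_BY(P_Y)_MZ(P_Z)`, optionally
#' followed by `" using name1vver1_name2vver2_..."` (the tool chain) and/or a
#' trailing `"{except label1, label2}"` exception clause. The three-block
#' core is whitespace-free; whitespace is tolerated around `using` and the
#' brace clause. Tool-chain entries are split at the last `"v"` that is
#' immediately followed by a digit, so `"BWAv0.7.5a"` yields name `"BWA"`
#' and version `"0.7.5a"`. Italics markup (asterisks) inside the exception
#' clause is stripped.
#'
#' @param text A single non-empty QSM string.
#' @return A [qsm_spec()] object.
#' @examples
#' parse_qsm("C50_B10(85)_M20(95)")
#' parse_qsm(paste0("C50_B10(85)_M20(95) using ",
#'                  "CASAVAv1.8.2_BWAv0.7.5a_Stampyv1.0.20_Platypusv0.2.4"))
#' @export
parse_qsm <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text)))
    stop("QSM string must be a single non-empty character value",
         call. = FALSE)
  s <- trimws(text)

  exceptions <- character()
  m <- regmatches(s, regexec("\\{\\s*except\\s+([^}]*)\\}\\s*$", s))[[1]]
  if (length(m)) {
    exceptions <- trimws(strsplit(gsub("\\*", "", m[2]), ",")[[1]])
    exceptions <- exceptions[nzchar(exceptions)]
    s <- trimws(sub("\\{\\s*except\\s+[^}]*\\}\\s*$", "", s))
  }

  toolchain <- NULL
  if (grepl("\\susing\\s", paste0(" ", s, " "))) {
    parts <- strsplit(s, "\\s+using\\s+")[[1]]
    if (length(parts) != 2L)
      stop("malformed tool-chain suffix in QSM string: ", sQuote(text),
           call. = FALSE)
    s <- trimws(parts[1])
    entries <- strsplit(trimws(parts[2]), "_", fixed = TRUE)[[1]]
    toolchain <- lapply(entries, split_tool_entry)
  }

  num <- "([0-9]+)"
  pct <- "([0-9]+(?:\\.[0-9]+)?)"
  core <- paste0("^C", num, "_B", num, "\\(", pct, "\\)_M", num,
                 "\\(", pct, "\\)$")
  g <- regmatches(s, regexec(core, s))[[1]]
  if (!length(g)) {
    # identify the offending block for the error message
    blocks <- strsplit(s, "_(?=[BM])", perl = TRUE)[[1]]
    offender <- "C/B/M core"
    if (length(blocks) == 3L) {
      pats <- c(C = paste0("^C", num, "$"),
                B = paste0("^B", num, "\\(", pct, "\\)$"),
                M = paste0("^M", num, "\\(", pct, "\\)$"))
      bad <- which(!mapply(grepl, pats, blocks))
      if (length(bad)) offender <- paste0(names(pats)[bad[1]], " block")
    } else if (!grepl("^C", s)) {
      offender <- "C block"
    }
    stop("malformed QSM string (", offender, "): ", sQuote(text),
         call. = FALSE)
  }
  vals <- as.numeric(g[-1])
  if (vals[3] > 100 || vals[5] > 100)
    stop("malformed QSM string (percentage outside [0,100] in ",
         if (vals[3] > 100) "B" else "M", " block): ", sQuote(text),
         call. = FALSE)
  qsm_spec(X = vals[1], Y = vals[2], P_Y = vals[3], Z = vals[4],
           P_Z = vals[5], toolchain = toolchain, exceptions = exceptions)
}

# "BWAv0.7.5a" -> c("BWA", "0.7.5a"): split at the LAST "v" followed by a
# digit; entries without such a "v" are kept whole with an empty version.
split_tool_entry <- function(entry) {
  m <- regexec("^(.*)v([0-9].*)$", entry)
  g <- regmatches(entry, m)[[1]]
  if (!length(g)) return(c(entry, ""))
  c(g[2], g[3])
}

#' Render a QSM specification as a string
#'
#' Renders the canonical QSM text in one of three styles: `"short"` (the
#' `CX_BY(P_Y)_MZ(P_Z)` core), `"full"` (the core plus
#' `" using <tool chain>"`) or `"summary"` (no threshold text at all). In
#' every style a non-empty exception list is appended as
#' `" {except label1, label2}"`. Rendering then parsing recovers the same
#' specification (the tool chain is only preserved by the full style).
#'
#' @param spec A [qsm_spec()] object.
#' @param style One of `"short"`, `"full"`, `"summary"`.
#' @return A single character string (possibly empty for `"summary"` with no
#'   exceptions).
#' @examples
#' render_qsm(qsm_spec(50, 10, 85, 20, 95))
#' @export
render_qsm <- function(spec, style = c("short", "full", "summary")) {
  stopifnot(inherits(spec, "qsm_spec"))
  style <- match.arg(style)
  core <- sprintf("C%d_B%d(%s)_M%d(%s)", spec$X, spec$Y, fmt_pct(spec$P_Y),
                  spec$Z, fmt_pct(spec$P_Z))
  out <- switch(style,
    short = core,
    full = {
      if (!nrow(spec$toolchain))
        stop("full style requires a non-empty tool chain", call. = FALSE)
      paste0(core, " using ",
             paste0(spec$toolchain$name, "v", spec$toolchain$version,
                    collapse = "_"))
    },
    summary = "")
  if (length(spec$exceptions)) {
    clause <- paste0("{except ", paste(spec$exceptions, collapse = ", "), "}")
    out <- if (nzchar(out)) paste(out, clause) else clause
  }
  out
}

#' Machine-readable JSON rendering of a QSM specification
#'
#' Serialises the five thresholds, tool chain and exception list to JSON for
#' embedding in pipeline metadata, with keys `X`, `Y`, `P_Y`, `Z`, `P_Z`,
#' `toolchain` (array of `{name, version}` objects) and `exceptions`.
#'
#' @param spec A [qsm_spec()] object.
#' @return A JSON string (class `json`).
#' @export
qsm_to_json <- function(spec) {
  stopifnot(inherits(spec, "qsm_spec"))
  tc <- spec$toolchain
  jsonlite::toJSON(
    list(X = spec$X, Y = spec$Y, P_Y = spec$P_Y, Z = spec$Z, P_Z = spec$P_Z,
         toolchain = tc, exceptions = spec$exceptions),
    auto_unbox = TRUE, digits = NA)
}

# Exact inclusive percentage test: does n_pass out of n_total reach at least
# pct percent?  Decided in scaled-integer arithmetic (pct carried to 1/100 of
# a percent) so the 85%/95% boundaries never suffer float artifacts.  A zero
# denominator passes only the vacuous pct == 0.
pct_at_least <- function(n_pass, n_total, pct) {
  p100 <- round(pct * 100)  # percent in hundredths, exact for <=2 decimals
  ifelse(n_total == 0L, p100 <= 0, 10000 * n_pass >= p100 * n_total)
}
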