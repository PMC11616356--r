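#' Write a trace to the pipeline trace format
#'
#' Plain tabular text: a mandatory header block of `# key: value` lines
#' (record id, sample rate, construct, substrate, temperature, processing
#' history) followed by tab-separated numeric columns `t`, `x` and
#' optionally `f`. Values are written with full double precision so a
#' read/write cycle is lossless.
#'
#' @param trace A `mot_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  assert_trace(trace)
  meta <- trace_meta(trace)
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    sprintf("# record_id: %s", meta$record_id %||% "record"),
    sprintf("# sample_rate: %.17g", sample_rate(trace)),
    sprintf("# construct: %s", meta$construct %||% NA),
    sprintf("# substrate: %s", meta$substrate %||% NA),
    sprintf("# temperature: %s", meta$temperature %||% NA),
    sprintf("# history: %s", paste(attr(trace, "history"), collapse = " | "))
  )
  writeLines(hdr, con)
  cols <- c("t", "x", if ("f" %in% names(trace)) "f")
  writeLines(paste(cols, collapse = "\t"), con)
  body <- do.call(paste, c(lapply(cols, function(cc) sprintf("%.17g", trace[[cc]])),
                           sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a trace from the pipeline trace format
#'
#' @param path File written by [write_trace()].
#' @return A `mot_trace`; malformed headers or non-uniform time stamps are
#'   rejected with a diagnostic naming the offending line.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) == 0 || hdr_idx[1] != 1) {
    stopf("%s: missing header block (line 1)", path)
  }
  hdr <- lines[hdr_idx]
  kv <- list()
  for (i in seq_along(hdr)) {
    m <- regmatches(hdr[i], regexec("^# *([^:]+): *(.*)$", hdr[i]))[[1]]
    if (length(m) != 3) stopf("%s: malformed header at line %d", path, i)
    kv[[trimws(m[2])]] <- trimws(m[3])
  }
  if (is.null(kv$sample_rate)) stopf("%s: header lacks sample_rate", path)
  body_start <- max(hdr_idx) + 1
  cols <- strsplit(lines[body_start], "\t")[[1]]
  if (!all(c("t", "x") %in% cols)) {
    stopf("%s: column header at line %d must contain t and x", path, body_start)
  }
  dat <- utils::read.table(
    text = lines[(body_start + 1):length(lines)], sep = "\t",
    col.names = cols, colClasses = "numeric"
  )
  num_or_na <- function(s) {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) s else v
  }
  tr <- tryCatch(
    new_trace(
      dat$t, dat$x, if ("f" %in% cols) dat$f,
      sample_rate = as.numeric(kv$sample_rate),
      meta = list(
        record_id = kv$record_id,
        construct = kv$construct,
        substrate = kv$substrate,
        temperature = num_or_na(kv$temperature)
      ),
      history = if (nzchar(kv$history %||% "")) {
        strsplit(kv$history, " \\| ")[[1]]
      } else {
        character()
      }
    ),
    error = function(e) stopf("%s: %s", path, conditionMessage(e))
  )
  tr
}

#' Write a distribution fit or configuration as structured text (JSON)
#'
#' @param x A `dist_fit`, `boot_test`, config list, or any serialisable
#'   list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(x, path) {
  if (inherits(x, "dist_fit")) x <- x[setdiff(names(x), "data")]
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
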