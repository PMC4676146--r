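#' Open a VCF file for streaming, record by record
#'
#' Opens a plain or gzip-compressed VCF 4.x file, parses the `#CHROM` header
#' line, and returns a reader whose `next_record()` closure yields one
#' variant record at a time. Memory use is bounded by a single record: the
#' file is never materialised in full, which is what makes whole-chromosome
#' scans feasible on a laptop.
#'
#' Only the GT subfield of each sample column is retained. Its position is
#' taken from the per-line FORMAT column; when the FORMAT column is absent
#' (fewer than 9 fixed columns is rejected, but a missing GT declaration is
#' tolerated) the entire sample column is treated as the genotype string.
#'
#' @param path path to a VCF file; gzip compression is detected
#'   automatically.
#' @return an object of class `vcf_reader` with elements:
#'   \describe{
#'     \item{sample_ids}{character vector of sample identifiers, in header
#'       order.}
#'     \item{n_fixed_columns}{always 9, the VCF fixed-column count.}
#'     \item{next_record}{function of no arguments returning the next
#'       variant record (a list with `chrom`, `pos`, `var_id`, `ref`,
#'       `alts`, `gt_strings`) or `NULL` at end of file.}
#'     \item{close}{function closing the underlying connection.}
#'   }
#' @seealso [read_vcf()] for a convenience wrapper that collects all
#'   records, [write_vcf()] for the inverse.
#' @export
open_vcf <- function(path) {
  if (!file.exists(path)) {
    stop_io("cannot open VCF file: ", path)
  }
  con <- gzfile(path, open = "rt")  # reads plain text transparently too
  line_no <- 0L
  header <- NULL
  repeat {
    line <- tryCatch(readLines(con, n = 1L),
                     error = function(e) {
                       close(con)
                       stop_io("error reading ", path, ": ", conditionMessage(e))
                     })
    if (length(line) == 0L) {
      close(con)
      stop_format("no #CHROM header line found in ", path)
    }
    line_no <- line_no + 1L
    if (startsWith(line, "##")) next
    if (startsWith(line, "#CHROM")) {
      fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
      if (length(fields) < 10L) {
        close(con)
        stop_format("header line declares no sample columns in ", path)
      }
      samples <- fields[-seq_len(9L)]
      if (anyDuplicated(samples) || any(!nzchar(samples))) {
        close(con)
        stop_format("sample IDs must be unique and non-empty in ", path)
      }
      header <- samples
      break
    }
    close(con)
    stop_format("unexpected line before #CHROM header at line ", line_no,
                " of ", path)
  }
  n_samples <- length(header)
  closed <- FALSE

  next_record <- function() {
    if (closed) return(NULL)
    line <- tryCatch(readLines(con, n = 1L),
                     error = function(e) {
                       stop_io("error reading ", path, ": ",
                               conditionMessage(e))
                     })
    if (length(line) == 0L) {
      close(con)
      closed <<- TRUE
      return(NULL)
    }
    line_no <<- line_no + 1L
    tryCatch(parse_vcf_data_line(line, n_samples, line_no, path),
             error = function(e) {
               close(con)
               closed <<- TRUE
               stop(e)
             })
  }

  structure(
    list(
      sample_ids = header,
      n_fixed_columns = 9L,
      next_record = next_record,
      close = function() {
        if (!closed) {
          close(con)
          closed <<- TRUE
        }
        invisible(NULL)
      }
    ),
    class = "vcf_reader"
  )
}

parse_vcf_data_line <- function(line, n_samples, line_no, path) {
  fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(fields) != 9L + n_samples) {
    stop_format("line ", line_no, " of ", path, " has ",
                length(fields) - 9L, " sample columns, expected ", n_samples)
  }
  pos <- suppressWarnings(as.integer(fields[2L]))
  if (is.na(pos) || pos < 1L) {
    stop_format("line ", line_no, " of ", path, ": invalid POS '",
                fields[2L], "'")
  }
  sample_cols <- fields[-seq_len(9L)]
  fmt <- fields[9L]
  if (fmt == "" || fmt == ".") {
    gt <- sample_cols
  } else {
    fmt_keys <- strsplit(fmt, ":", fixed = TRUE)[[1L]]
    gi <- match("GT", fmt_keys)
    if (is.na(gi)) {
      gt <- sample_cols
    } else if (gi == 1L) {
      gt <- sub(":.*", "", sample_cols)
    } else {
      gt <- vapply(strsplit(sample_cols, ":", fixed = TRUE),
                   function(x) if (length(x) >= gi) x[[gi]] else ".",
                   character(1L))
    }
  }
  list(
    chrom = fields[1L],
    pos = pos,
    var_id = fields[3L],
    ref = fields[4L],
    alts = strsplit(fields[5L], ",", fixed = TRUE)[[1L]],
    gt_strings = gt
  )
}

#' Read an entire VCF file into memory
#'
#' Convenience wrapper around [open_vcf()] for small files: collects every
#' record into a list. One or more paths may be given (e.g. per-chromosome
#' files); they are concatenated in the order given, and every file must
#' declare the same samples in the same order.
#'
#' @param paths one or more VCF paths.
#' @return list with `sample_ids` and `records` (list of variant records).
#' @export
read_vcf <- function(paths) {
  records <- list()
  sample_ids <- NULL
  for (path in paths) {
    rdr <- open_vcf(path)
    if (is.null(sample_ids)) {
      sample_ids <- rdr$sample_ids
    } else if (!identical(sample_ids, rdr$sample_ids)) {
      rdr$close()
      stop_format("sample columns of ", path,
                  " do not match the first input file")
    }
    repeat {
      rec <- rdr$next_record()
      if (is.null(rec)) break
      records[[length(records) + 1L]] <- rec
    }
  }
  list(sample_ids = sample_ids, records = records)
}

#' @export
print.vcf_reader <- function(x, ...) {
  cat("VCF reader:", length(x$sample_ids), "samples\n")
  invisible(x)
}

#' Write variant records as a VCF file
#'
#' Emits a minimal VCF 4.2 file carrying genotypes only: the FORMAT column
#' is `GT` and each sample column is the genotype string. The output
#' re-parses through [read_vcf()] to the identical header and record
#' sequence.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param records list of variant records (as returned by [read_vcf()]), or
#'   a function of no arguments yielding one record per call and `NULL` when
#'   exhausted (so large cohorts can be written without materialising them).
#' @param dest output path; a `.gz` suffix or `gzipped = TRUE` compresses.
#' @param gzipped write gzip-compressed output.
#' @return number of records written, invisibly.
#' @export
write_vcf <- function(sample_ids, records, dest,
                      gzipped = grepl("\\.gz$", dest)) {
  if (anyDuplicated(sample_ids) || any(!nzchar(sample_ids))) {
    stop_param("sample IDs must be unique and non-empty")
  }
  con <- tryCatch(
    if (gzipped) gzfile(dest, open = "wt") else file(dest, open = "wt"),
    error = function(e) stop_io("cannot open ", dest, " for writing"),
    warning = function(w) stop_io("cannot open ", dest, " for writing")
  )
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=popclust",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  ), con)
  pull <- if (is.function(records)) {
    records
  } else {
    i <- 0L
    function() {
      i <<- i + 1L
      if (i > length(records)) NULL else records[[i]]
    }
  }
  n <- 0L
  repeat {
    rec <- pull()
    if (is.null(rec)) break
    if (length(rec$gt_strings) != length(sample_ids)) {
      stop_param("record ", n + 1L, " has ", length(rec$gt_strings),
                 " genotypes, expected ", length(sample_ids))
    }
    writeLines(paste(c(rec$chrom, rec$pos, rec$var_id, rec$ref,
                       paste(rec$alts, collapse = ","),
                       ".", ".", ".", "GT", rec$gt_strings),
                     collapse = "\t"), con)
    n <- n + 1L
  }
  invisible(n)
}
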