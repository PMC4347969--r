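#' Quality and adapter filtering of FASTQ reads
#'
#' Whole-read exclusion filter: a read is dropped iff more than
#' `max_lowq_frac` of its bases have a Phred quality at or below
#' `q_threshold` ("more than" is strict, "at or below" inclusive), or any
#' of the given adapter/primer sequences occurs as an exact substring on
#' the forward strand.  Reads are never trimmed; surviving reads are
#' written unchanged, preserving input order.
#'
#' @param fastq_in input FASTQ path (optionally gzipped).
#' @param fastq_out output FASTQ path for kept reads, or `NULL` to only
#'   report.
#' @param q_threshold Phred score at or below which a base counts as
#'   low-quality (default 20).
#' @param max_lowq_frac maximum tolerated fraction of low-quality bases
#'   (default 0.30; strictly exceeding it drops the read).
#' @param adapters character vector of adapter/primer sequences; empty
#'   disables adapter screening.
#' @param encoding `"phred33"` (default) or `"phred64"`.
#' @return list of class `readFilterReport`: `n_input`, `n_kept`,
#'   `n_dropped_lowq`, `n_dropped_adapter`, `kept_ids`.  A read failing
#'   both rules is counted under the quality reason.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' simulateFastq(fq, 20, read_len = 50, frac_lowq = 0.5, seed = 1)
#' filterReads(fq)
#' @export
filterReads <- function(fastq_in, fastq_out = NULL, q_threshold = 20,
                        max_lowq_frac = 0.30, adapters = character(),
                        encoding = c("phred33", "phred64")) {
    encoding <- match.arg(encoding)
    reads <- withCallingHandlers(
        tryCatch(
            Biostrings::readQualityScaledDNAStringSet(
                fastq_in,
                quality.scoring = if (encoding == "phred33") "phred"
                                  else "illumina"),
            error = function(e) stop("malformed FASTQ '", fastq_in,
                                     "': ", conditionMessage(e),
                                     call. = FALSE)),
        warning = function(w) {
            # Biostrings emits an informational warning about dropped
            # metadata columns when rebuilding the string set
            if (grepl("metadata columns", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    q <- methods::as(Biostrings::quality(reads), "IntegerList")
    lens <- Biostrings::width(reads)
    stopIf(any(lens == 0), "zero-length read in '", fastq_in, "'")
    nlow <- sum(q <= q_threshold)
    low_frac <- nlow / lens
    drop_q <- low_frac > max_lowq_frac
    drop_a <- rep(FALSE, length(reads))
    if (length(adapters)) {
        dna <- methods::as(reads, "DNAStringSet")
        for (ad in adapters)
            drop_a <- drop_a | Biostrings::vcountPattern(ad, dna) > 0
    }
    keep <- !(drop_q | drop_a)
    if (!is.null(fastq_out)) {
        out <- reads[keep]
        S4Vectors::mcols(out) <- NULL
        Biostrings::writeQualityScaledXStringSet(out, fastq_out)
    }
    structure(list(n_input = length(reads), n_kept = sum(keep),
                   n_dropped_lowq = sum(drop_q),
                   n_dropped_adapter = sum(drop_a & !drop_q),
                   kept_ids = names(reads)[keep]),
              class = "readFilterReport")
}

#' @export
print.readFilterReport <- function(x, ...) {
    cat(sprintf("reads: %d in, %d kept, %d dropped (quality), %d dropped (adapter)\n",
                x$n_input, x$n_kept, x$n_dropped_lowq,
                x$n_dropped_adapter))
    invisible(x)
}

#' Write a read-filter report as TSV
#' @param report a [filterReads()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFilterReport <- function(report, path) {
    writeTSV(data.frame(reason = c("input", "kept", "dropped_lowq",
                                   "dropped_adapter"),
                        count = c(report$n_input, report$n_kept,
                                  report$n_dropped_lowq,
                                  report$n_dropped_adapter)),
             path)
}
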