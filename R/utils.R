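# internal helpers

# evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        has_old <- exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE)
        if (has_old) old <- get(".Random.seed", envir = globalenv())
        on.exit({
            if (has_old) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
        set.seed(seed)
    }
    force(expr)
}

# spawn a stream of sub-seeds from one master seed, deterministically,
# keeping them within 32-bit integer range
spawnSeeds <- function(seed, n) {
    withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopIf <- function(cond, ...) if (cond) stop(..., call. = FALSE)

#' Write a data frame as tab-separated values
#'
#' Plain TSV writer used for every pipeline artifact: no quoting, no row
#' names, `NA` written as literal `NA`.
#'
#' @param df data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTSV <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read a tab-separated file written by [writeTSV()]
#' @param path file path.
#' @return data frame.
#' @export
readTSV <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE)
}
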