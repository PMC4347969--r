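#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#'   colData<- rowData<-
NULL

#' Container for gene x sample heat-gradient count data
#'
#' `HeatCounts` extends [SummarizedExperiment::SummarizedExperiment] and
#' carries a single `counts` assay together with the sample annotation the
#' gradient analysis needs: the genotype (inbred line), the heat level in
#' degrees Celsius, the replication index, the library size and (once
#' computed) a TMM normalization factor.  Simulated objects additionally
#' carry the planted per-gene truth in `rowData` and the planted
#' per-genotype susceptibility in `metadata(x)$hsi`.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#'
#' @seealso [HeatCounts()] for construction, [simulateCounts()] for
#'   simulation with planted effects.
#' @export
setClass("HeatCounts", contains = "SummarizedExperiment")

setValidity("HeatCounts", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- SummarizedExperiment::assay(object, "counts")
        if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
    }
    need <- c("genotype", "heat_c", "rep", "lib_size")
    miss <- setdiff(need, colnames(colData(object)))
    if (length(miss))
        msg <- c(msg, paste0("colData is missing column(s): ",
                             paste(miss, collapse = ", ")))
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample IDs must be unique")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene IDs must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct a HeatCounts object
#'
#' @param counts integer matrix of read counts, genes in rows (rownames =
#'   gene IDs), samples in columns (colnames = sample IDs).
#' @param genotype factor or character, genotype label per sample.
#' @param heat_c numeric, heat level per sample in degrees Celsius.
#' @param rep replication index per sample.
#' @param lib_size library size per sample; defaults to the column sums.
#' @param norm_factor normalization factor per sample (default 1; see
#'   [tmmFactors()]).
#' @param ... further columns stored in `colData`.
#'
#' @return A [HeatCounts-class] object.
#' @examples
#' m <- matrix(rpois(40, 50), nrow = 10,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' hc <- HeatCounts(m, genotype = c("A", "A", "B", "B"),
#'                  heat_c = c(25, 38, 25, 38), rep = c(1, 1, 1, 1))
#' libSizes(hc)
#' @export
HeatCounts <- function(counts, genotype, heat_c, rep,
                       lib_size = colSums(counts), norm_factor = 1, ...) {
    counts <- as.matrix(counts)
    cd <- DataFrame(genotype = as.character(genotype),
                    heat_c = as.numeric(heat_c),
                    rep = rep,
                    lib_size = as.numeric(lib_size),
                    norm_factor = as.numeric(norm_factor),
                    ...,
                    row.names = colnames(counts))
    methods::new("HeatCounts",
                 SummarizedExperiment(assays = list(counts = counts),
                                      colData = cd))
}

#' @describeIn HeatCounts library sizes per sample.
#' @param x,object a `HeatCounts` object.
#' @export
libSizes <- function(x) {
    stopifnot(methods::is(x, "HeatCounts"))
    stats::setNames(colData(x)$lib_size, colnames(x))
}

#' @describeIn HeatCounts normalization factors per sample.
#' @export
normFactors <- function(x) {
    stopifnot(methods::is(x, "HeatCounts"))
    nf <- colData(x)$norm_factor
    if (is.null(nf)) nf <- rep(1, ncol(x))
    stats::setNames(nf, colnames(x))
}

#' @describeIn HeatCounts set normalization factors.
#' @param value numeric vector of positive factors, one per sample.
#' @export
`normFactors<-` <- function(x, value) {
    stopifnot(methods::is(x, "HeatCounts"), length(value) == ncol(x),
              all(value > 0))
    colData(x)$norm_factor <- as.numeric(value)
    x
}

#' @describeIn HeatCounts sorted unique heat levels (degrees C).
#' @export
heatLevels <- function(x) {
    stopifnot(methods::is(x, "HeatCounts"))
    sort(unique(colData(x)$heat_c))
}

#' @describeIn HeatCounts unique genotype labels.
#' @export
genotypes <- function(x) {
    stopifnot(methods::is(x, "HeatCounts"))
    unique(colData(x)$genotype)
}

#' @describeIn HeatCounts planted simulation truth (`NULL` for real data).
#' @export
simTruth <- function(x) {
    stopifnot(methods::is(x, "HeatCounts"))
    rd <- rowData(x)
    if (!"status" %in% colnames(rd)) return(NULL)
    rd
}

#' @rdname HeatCounts
#' @export
setMethod("show", "HeatCounts", function(object) {
    methods::callNextMethod()
    cat(sprintf("genotypes(%d): %s\n", length(genotypes(object)),
                paste(utils::head(genotypes(object), 8), collapse = " ")))
    cat(sprintf("heat levels (C): %s\n",
                paste(heatLevels(object), collapse = " ")))
    if (!is.null(simTruth(object)))
        cat("simulated object with planted truth in rowData\n")
})
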