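# Readers and writers for the standard formats touched: genetic maps
# (HapMap dialect), read-count TSV, phased VCF, truth tracks, segmentation
# and ancestry outputs (TSV + BED-like, 0-based half-open), JSON metrics.

#' Read a genetic map
#'
#' Accepts the HapMap-map dialect — whitespace/tab text with columns
#' position, rate (cM/Mb) and cumulative cM, with or without a header — and
#' a minimal 2-column (position, cumulative cM) dialect.
#'
#' @param path file path.
#' @return A [GeneticMap-class].
#' @export
readGeneticMap <- function(path) {
    first <- readLines(path, n = 1L)
    hasHeader <- !grepl("^\\s*[0-9]", first)
    tab <- read.table(path, header = hasHeader)
    if (ncol(tab) >= 3L) GeneticMap(tab[[1L]], tab[[3L]])
    else if (ncol(tab) == 2L) GeneticMap(tab[[1L]], tab[[2L]])
    else stop("genetic map must have 2 (pos, cM) or 3 (pos, rate, cM) columns")
}

#' Write / read per-individual biallelic read counts as TSV
#'
#' Columns: `snp_id`, `pos`, then two columns per individual
#' (`ref_<id>`, `alt_<id>`).
#'
#' @param rc a [ReadCounts-class].
#' @param path file path.
#' @param ids optional individual identifiers (default `ind1..indN`).
#' @return `writeReadCounts` returns `path` invisibly; `readReadCounts`
#'   returns a [ReadCounts-class].
#' @export
writeReadCounts <- function(rc, path, ids = NULL) {
    stopifnot(is(rc, "ReadCounts"))
    N <- nrow(rc@refCount); L <- ncol(rc@refCount)
    if (is.null(ids)) ids <- paste0("ind", seq_len(N))
    df <- data.frame(snp_id = paste0("snp", seq_len(L)), pos = rc@positions)
    for (i in seq_len(N)) {
        df[[paste0("ref_", ids[i])]] <- rc@refCount[i, ]
        df[[paste0("alt_", ids[i])]] <- rc@altCount[i, ]
    }
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeReadCounts
#' @export
readReadCounts <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
    refCols <- grep("^ref_", names(df))
    altCols <- grep("^alt_", names(df))
    if (!length(refCols) || length(refCols) != length(altCols))
        stop("read-count TSV needs paired ref_/alt_ columns")
    new("ReadCounts",
        refCount = t(as.matrix(df[refCols])),
        altCount = t(as.matrix(df[altCols])),
        positions = as.numeric(df$pos))
}

#' Read phased haplotypes (or genotype dosages) from a VCF
#'
#' Biallelic SNPs only; multi-allelic records are skipped with a warning.
#' In haplotype mode the GT field must be phased (`|`-separated) and
#' complete; unphased or missing genotypes are an error. In genotype mode
#' `/`-separated genotypes are accepted and summed into dosages.
#'
#' @param path VCF file path (plain text).
#' @param mode `"haplotypes"` (default) or `"genotypes"`.
#' @return list with `data` (2N x L 0/1 matrix, or N x L dosage matrix),
#'   `positions`, `chrom` and `ids`.
#' @export
readPhasedVcf <- function(path, mode = c("haplotypes", "genotypes")) {
    mode <- match.arg(mode)
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    multi <- grepl(",", vcf@fix[, "ALT"])
    if (any(multi)) {
        warning(sum(multi), " multi-allelic site(s) skipped")
        vcf <- vcf[!multi, ]
    }
    gt <- vcfR::extract.gt(vcf, element = "GT")
    positions <- as.numeric(vcf@fix[, "POS"])
    chrom <- vcf@fix[, "CHROM"]
    ids <- colnames(gt)
    if (any(is.na(gt)) || any(grepl("\\.", gt)))
        stop("missing genotypes in VCF")
    if (mode == "haplotypes") {
        if (any(grepl("/", gt, fixed = TRUE)))
            stop("unphased genotypes not allowed in haplotype mode")
        a1 <- suppressWarnings(as.integer(sub("\\|.*", "", gt)))
        a2 <- suppressWarnings(as.integer(sub(".*\\|", "", gt)))
        if (any(is.na(a1)) || any(is.na(a2))) stop("malformed GT field")
        L <- nrow(gt); N <- ncol(gt)
        H <- matrix(0L, 2L * N, L)
        H[seq(1L, 2L * N, 2L), ] <- t(matrix(a1, L, N))
        H[seq(2L, 2L * N, 2L), ] <- t(matrix(a2, L, N))
        list(data = H, positions = positions, chrom = chrom, ids = ids)
    } else {
        a1 <- suppressWarnings(as.integer(sub("[|/].*", "", gt)))
        a2 <- suppressWarnings(as.integer(sub(".*[|/]", "", gt)))
        if (any(is.na(a1)) || any(is.na(a2))) stop("malformed GT field")
        G <- t(matrix(a1 + a2, nrow(gt), ncol(gt)))
        list(data = G, positions = positions, chrom = chrom, ids = ids)
    }
}

#' Write phased haplotypes to a (plain-text) VCF
#'
#' Minimal VCFv4.2 writer with phased GT fields; the inverse of
#' [readPhasedVcf()].
#'
#' @param H 2N x L 0/1 haplotype matrix (chains of individual i on rows
#'   2i-1, 2i).
#' @param positions SNP bp positions.
#' @param path output path.
#' @param chrom chromosome name (default `"1"`).
#' @param ids optional sample identifiers.
#' @return `path`, invisibly.
#' @export
writePhasedVcf <- function(H, positions, path, chrom = "1", ids = NULL) {
    N <- nrow(H) %/% 2L; L <- ncol(H)
    if (is.null(ids)) ids <- paste0("ind", seq_len(N))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##source=mosaicAncestry",
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", ids), collapse = "\t")),
               con)
    gtCols <- vapply(seq_len(N), function(i)
        paste0(H[2L * i - 1L, ], "|", H[2L * i, ]), character(L))
    if (L == 1L) gtCols <- matrix(gtCols, nrow = 1L)
    lines <- paste(chrom, format(positions, scientific = FALSE, trim = TRUE),
                   paste0("snp", seq_len(L)), "A", "T", ".", "PASS", ".",
                   "GT", apply(gtCols, 1L, paste, collapse = "\t"),
                   sep = "\t")
    writeLines(lines, con)
    invisible(path)
}

# collapse per-SNP labels of one chain into 0-based half-open BED intervals
.bedIntervals <- function(labels, positions, chrom) {
    rl <- rle(labels)
    ends <- cumsum(rl$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    # interval [pos[start], pos of next segment start) in bp, half-open
    bedStart <- positions[starts] - 1
    bedEnd <- c(positions[ends[-length(ends)] + 1L] - 1, positions[ends[length(ends)]])
    data.frame(chrom = chrom, start = bedStart, end = bedEnd,
               label = rl$values)
}

#' Write a simulated truth track
#'
#' TSV columns: chrom, pos, individual, haplotype (1|2), true_pop; plus an
#' optional BED-like segment file (0-based half-open) per haplotype.
#'
#' @param sample an [AdmixedSample-class].
#' @param path TSV output path.
#' @param bedPath optional BED output path.
#' @param chrom chromosome name.
#' @return `path`, invisibly.
#' @export
writeTruthTrack <- function(sample, path, bedPath = NULL, chrom = "1") {
    stopifnot(is(sample, "AdmixedSample"))
    C <- nrow(sample@truth); L <- ncol(sample@truth)
    df <- data.frame(
        chrom = chrom,
        pos = rep(sample@positions, each = C),
        individual = rep(rep(seq_len(C %/% 2L), each = 2L), L),
        haplotype = rep(rep(1:2, C %/% 2L), L),
        true_pop = as.vector(sample@truth))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(bedPath)) {
        beds <- lapply(seq_len(C), function(cc) {
            b <- .bedIntervals(sample@truth[cc, ], sample@positions, chrom)
            b$individual <- (cc + 1L) %/% 2L
            b$haplotype <- 2L - (cc %% 2L)
            b
        })
        write.table(do.call(rbind, beds), bedPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    invisible(path)
}

#' Write an ancestry fit
#'
#' Per-SNP TSV (chrom, pos, individual, haplotype, MAP label, posterior
#' label frequencies) and an optional BED-like collapsed segment file
#' (0-based half-open) per haplotype.
#'
#' @param fit an [AncestryFit-class].
#' @param path TSV output path.
#' @param bedPath optional BED output path.
#' @param chrom chromosome name.
#' @param header optional character vector of `##`-style comment lines
#'   (e.g. the seed and configuration) prepended to the TSV.
#' @return `path`, invisibly.
#' @export
writeAncestry <- function(fit, path, bedPath = NULL, chrom = "1",
                          header = NULL) {
    stopifnot(is(fit, "AncestryFit"))
    C <- nrow(fit@mapLabels); L <- ncol(fit@mapLabels)
    nLab <- max(fit@nPops, 1L)
    post <- fit@labelCounts[seq_len(nLab), , , drop = FALSE] /
        max(1L, fit@nSamples)
    df <- data.frame(
        chrom = chrom,
        pos = rep(fit@positions, each = C),
        individual = rep(rep(seq_len(C %/% 2L), each = 2L), L),
        haplotype = rep(rep(1:2, C %/% 2L), L),
        map_label = as.vector(fit@mapLabels))
    for (q in seq_len(nLab))
        df[[paste0("p", q)]] <- round(as.vector(post[q, , ]), 4L)
    con <- file(path, "w")
    if (!is.null(header)) writeLines(paste0("## ", header), con)
    close(con)
    suppressWarnings(
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                    append = !is.null(header)))
    if (!is.null(bedPath)) {
        beds <- lapply(seq_len(C), function(cc) {
            b <- .bedIntervals(fit@mapLabels[cc, ], fit@positions, chrom)
            b$individual <- (cc + 1L) %/% 2L
            b$haplotype <- 2L - (cc %% 2L)
            b
        })
        write.table(do.call(rbind, beds), bedPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    invisible(path)
}

#' Write a haplotype segmentation
#'
#' Segmentation TSV (individual, haplotype, a, b, state) and per-SNP
#' recombination probability TSV (snp, r).
#'
#' @param hs a [HaplotypeStructure-class].
#' @param path segmentation TSV path.
#' @param rPath optional r_j TSV path.
#' @return `path`, invisibly.
#' @export
writeSegmentation <- function(hs, path, rPath = NULL) {
    segs <- segmentsFromStructure(hs)
    write.table(segs@segments, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(rPath))
        write.table(data.frame(snp = seq_along(hs@r), r = hs@r), rPath,
                    sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write evaluation metrics as JSON
#'
#' @param metrics named list of metric values.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMetricsJson <- function(metrics, path) {
    jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
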