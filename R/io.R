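#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   DNAString reverseComplement alphabetFrequency PhredQuality
#'   QualityScaledDNAStringSet quality width subseq
#' @importFrom GenomicAlignments GAlignments cigarWidthAlongQuerySpace
#'   cigarWidthAlongReferenceSpace cigarRangesAlongQuerySpace
#'   cigarRangesAlongReferenceSpace
#' @importFrom S4Vectors metadata metadata<- Rle
#' @importFrom BiocGenerics strand
#' @importFrom IRanges IRanges
#' @importFrom data.table data.table setkeyv setorderv rbindlist fread :=
#'   .N .SD
NULL

## positions are 1-based inclusive everywhere: internally (the R convention
## shared with GRanges/IRanges) and in every TSV this package reads or writes.

#' Read a reference genome from FASTA
#'
#' Loads a (multi-)FASTA assembly into a named `DNAStringSet`. Sequence names
#' are truncated at the first whitespace, lowercase bases are uppercased, and
#' only A/C/G/T/N are accepted.
#'
#' @param path path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] with one element per contig,
#'   order preserved.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ac", "gt"), fa)
#' readReferenceGenome(fa)
#' @export
readReferenceGenome <- function(path) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    genome <- readDNAStringSet(path, format = "fasta")
    names(genome) <- sub("\\s.*$", "", names(genome))
    if (any(!nzchar(names(genome))))
        stop("FASTA contains a record with an empty name")
    dup <- unique(names(genome)[duplicated(names(genome))])
    if (length(dup))
        stop("duplicate contig name(s) in FASTA: ", paste(dup, collapse = ", "))
    if (any(width(genome) == 0L)) {
        bad <- names(genome)[width(genome) == 0L]
        stop("empty sequence for record(s): ", paste(bad, collapse = ", "))
    }
    freq <- alphabetFrequency(genome)
    allowed <- colnames(freq) %in% c("A", "C", "G", "T", "N")
    extra <- rowSums(freq[, !allowed, drop = FALSE])
    if (any(extra > 0)) {
        bad <- names(genome)[extra > 0]
        stop("non-ACGTN characters in record(s): ", paste(bad, collapse = ", "))
    }
    genome
}

#' Write a genome to FASTA
#'
#' @param genome a named `DNAStringSet`.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
writeReferenceGenome <- function(genome, path, width = 70L) {
    writeXStringSet(genome, path, format = "fasta", width = width)
    invisible(path)
}

#' Read sequencing reads from FASTQ or FASTA
#'
#' FASTQ (4-line records, Phred+33) yields a `QualityScaledDNAStringSet`;
#' FASTA yields a plain `DNAStringSet` (no qualities, so quality trimming is
#' bypassed for such input). The format is detected from the first
#' non-empty character (`@` vs `>`).
#'
#' @param path path to a FASTQ or FASTA file.
#' @return A [Biostrings::QualityScaledDNAStringSet] (FASTQ) or
#'   [Biostrings::DNAStringSet] (FASTA), named by read id.
#' @export
readReads <- function(path) {
    if (!file.exists(path))
        stop("read file not found: ", path)
    con <- file(path, "r"); on.exit(close(con))
    first <- ""
    while (!nzchar(first)) {
        line <- readLines(con, n = 1L)
        if (!length(line)) break
        first <- substr(trimws(line), 1L, 1L)
    }
    if (identical(first, ">")) {
        reads <- readDNAStringSet(path, format = "fasta")
        names(reads) <- sub("\\s.*$", "", names(reads))
        return(reads)
    }
    seqs <- readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    quals <- PhredQuality(mcols(seqs)$qualities)
    ids <- sub("\\s.*$", "", names(seqs))
    mcols(seqs) <- NULL
    out <- QualityScaledDNAStringSet(DNAStringSet(seqs), quals)
    names(out) <- ids
    out
}

#' Write reads to FASTQ (or FASTA when no qualities are present)
#'
#' @param reads a `QualityScaledDNAStringSet` or `DNAStringSet`.
#' @param path output path; FASTQ for quality-scaled input, FASTA otherwise.
#' @return `path`, invisibly.
#' @export
writeReads <- function(reads, path) {
    if (is(reads, "QualityScaledDNAStringSet")) {
        writeXStringSet(DNAStringSet(reads), path, format = "fastq",
                        qualities = quality(reads))
    } else {
        writeXStringSet(reads, path, format = "fasta")
    }
    invisible(path)
}

.CIGAR_RE <- "^([0-9]+[MIDNSHX=])+$"

#' Read SAM alignments
#'
#' Parses a SAM text file (header required) into a
#' [GenomicAlignments::GAlignments] with metadata columns `qname`, `flag`,
#' `mapq` and `seq`. Unmapped records (flag 0x4) are skipped and counted in
#' `metadata(x)$nSkippedUnmapped`. CIGAR ops M/=/X/I/D/N/S/H are accepted;
#' for every record the query-consuming CIGAR length must equal the sequence
#' length.
#'
#' @param path path to a SAM file.
#' @param reference optional `DNAStringSet`; when given, `@SQ` contig names
#'   are checked against it and records on unknown contigs raise an error.
#' @return A `GAlignments` object (one element per mapped record, input
#'   order preserved).
#' @export
readSamAlignments <- function(path, reference = NULL) {
    if (!file.exists(path))
        stop("SAM file not found: ", path)
    lines <- readLines(path)
    is_hdr <- startsWith(lines, "@")
    if (!any(is_hdr))
        stop("SAM file has no header: ", path)
    hdr <- lines[is_hdr]
    sq <- hdr[startsWith(hdr, "@SQ")]
    sq_names <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    if (!is.null(reference) && length(sq)) {
        unknown <- setdiff(sq_names, names(reference))
        if (length(unknown))
            stop("@SQ contig(s) absent from reference: ",
                 paste(unknown, collapse = ", "))
    }
    body <- lines[!is_hdr]
    body <- body[nzchar(body)]
    if (!length(body)) {
        gal <- GAlignments(seqnames = factor(), pos = integer(),
                           cigar = character(), strand = strand())
        mcols(gal) <- DataFrame(qname = character(), flag = integer(),
                                mapq = integer(), seq = DNAStringSet())
        metadata(gal)$nSkippedUnmapped <- 0L
        return(gal)
    }
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 11L))
        stop("malformed SAM record (fewer than 11 fields) at line ",
             which(!is_hdr)[which(nf < 11L)[1L]])
    qname <- vapply(fields, `[[`, "", 1L)
    flag  <- as.integer(vapply(fields, `[[`, "", 2L))
    rname <- vapply(fields, `[[`, "", 3L)
    pos   <- as.integer(vapply(fields, `[[`, "", 4L))
    mapq  <- as.integer(vapply(fields, `[[`, "", 5L))
    cigar <- vapply(fields, `[[`, "", 6L)
    seqs  <- vapply(fields, `[[`, "", 10L)

    unmapped <- bitwAnd(flag, 4L) != 0L | rname == "*" | cigar == "*"
    n_skipped <- sum(unmapped)
    keep <- !unmapped
    qname <- qname[keep]; flag <- flag[keep]; rname <- rname[keep]
    pos <- pos[keep]; mapq <- mapq[keep]; cigar <- cigar[keep]
    seqs <- seqs[keep]

    if (length(cigar)) {
        bad <- !grepl(.CIGAR_RE, cigar)
        if (any(bad))
            stop("unknown or malformed CIGAR '", cigar[bad][1L],
                 "' for read ", qname[bad][1L])
        qw <- cigarWidthAlongQuerySpace(cigar)  # M, I, S, =, X
        mismatch <- qw != nchar(seqs)
        if (any(mismatch))
            stop("CIGAR/sequence length mismatch for read ",
                 qname[mismatch][1L], " (CIGAR implies ",
                 qw[mismatch][1L], ", sequence has ",
                 nchar(seqs[mismatch][1L]), ")")
        if (any(pos < 1L))
            stop("non-positive alignment position for read ",
                 qname[pos < 1L][1L])
    }
    if (!is.null(reference)) {
        unknown <- setdiff(unique(rname), names(reference))
        if (length(unknown))
            stop("alignment references unknown contig(s): ",
                 paste(unknown, collapse = ", "))
    }
    lev <- if (!is.null(reference)) names(reference) else
        unique(c(sq_names, rname))
    gal <- GAlignments(
        seqnames = Rle(factor(rname, levels = lev)),
        pos = pos, cigar = cigar,
        strand = strand(ifelse(bitwAnd(flag, 16L) != 0L, "-", "+")))
    mcols(gal) <- DataFrame(qname = qname, flag = flag, mapq = mapq,
                            seq = DNAStringSet(seqs))
    metadata(gal)$nSkippedUnmapped <- n_skipped
    gal
}

#' Write alignments to SAM
#'
#' Emits a minimal valid SAM file (`@HD` + `@SQ` header from the reference,
#' `*` base qualities) from a `GAlignments` carrying the metadata columns
#' produced by [readSamAlignments()] or [placeAlignments()].
#'
#' @param aln a `GAlignments` with mcols `qname`, `flag`, `mapq`, `seq`.
#' @param reference named `DNAStringSet` providing `@SQ` lines.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSamAlignments <- function(aln, reference, path) {
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(reference), width(reference)))
    if (length(aln)) {
        mc <- mcols(aln)
        rec <- paste(mc$qname, mc$flag,
                     as.character(GenomicAlignments::seqnames(aln)),
                     GenomicAlignments::start(aln), mc$mapq,
                     GenomicAlignments::cigar(aln),
                     "*", 0L, 0L, as.character(mc$seq), "*",
                     sep = "\t")
    } else rec <- character()
    writeLines(c(hdr, rec), path)
    invisible(path)
}

#' Read genome-to-genome alignment blocks (show-coords tab dialect)
#'
#' Parses the tabular output of whole-genome aligners in the `show-coords`
#' column convention: `old_start old_end new_start new_end old_len new_len
#' pct_identity old_contig new_contig`. Header/banner lines (first field
#' non-numeric, or fewer than 9 fields) are skipped. A row whose new-assembly
#' interval has start greater than end encodes reverse orientation and is
#' flagged.
#'
#' @param path path to the coords file.
#' @return A `data.frame` with columns `old_contig`, `old_start`, `old_end`,
#'   `new_contig`, `new_start`, `new_end`, `pct_identity`, `reverse`.
#' @export
readCoordsBlocks <- function(path) {
    if (!file.exists(path))
        stop("coords file not found: ", path)
    lines <- readLines(path)
    out <- vector("list", length(lines))
    n <- 0L
    for (i in seq_along(lines)) {
        ln <- trimws(lines[i])
        if (!nzchar(ln)) next
        f <- strsplit(ln, "[ \t|]+")[[1L]]
        f <- f[nzchar(f)]
        if (length(f) < 9L) next
        if (!grepl("^-?[0-9]+$", f[1L])) next           # header/banner line
        num <- suppressWarnings(as.numeric(f[1:7]))
        if (anyNA(num))
            stop("non-numeric coordinate field at line ", i, ": ", lines[i])
        blk <- data.frame(old_contig = f[8L],
                          old_start = num[1L], old_end = num[2L],
                          new_contig = f[9L],
                          new_start = num[3L], new_end = num[4L],
                          pct_identity = num[7L],
                          stringsAsFactors = FALSE)
        if (blk$old_start > blk$old_end)
            stop("degenerate old-assembly interval at line ", i)
        if (blk$pct_identity <= 0 || blk$pct_identity > 100)
            stop("percent identity out of (0, 100] at line ", i)
        blk$reverse <- blk$new_start > blk$new_end
        n <- n + 1L
        out[[n]] <- blk
    }
    if (n == 0L)
        return(data.frame(old_contig = character(), old_start = numeric(),
                          old_end = numeric(), new_contig = character(),
                          new_start = numeric(), new_end = numeric(),
                          pct_identity = numeric(), reverse = logical(),
                          stringsAsFactors = FALSE))
    do.call(rbind, out[seq_len(n)])
}

#' Write a candidate-site or verdict table to TSV
#'
#' Writes one row per call with 1-based positions, tab-separated, UTF-8, with
#' a header row. Rows are ordered by (contig, pos, alt). Any extra columns
#' (e.g. `category`, `evidence` from [classifySites()]) are preserved.
#'
#' @param sites a `data.frame` with at least columns `contig`, `pos`, `ref`,
#'   `alt`, `depth`, `alt_count`, `alt_frac`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSitesTable <- function(sites, path) {
    need <- c("contig", "pos", "ref", "alt", "depth", "alt_count", "alt_frac")
    miss <- setdiff(need, names(sites))
    if (length(miss))
        stop("sites table lacks column(s): ", paste(miss, collapse = ", "))
    front <- c(need, setdiff(names(sites), need))
    sites <- sites[, front, drop = FALSE]
    if (nrow(sites))
        sites <- sites[order(sites$contig, sites$pos, sites$alt), ,
                       drop = FALSE]
    utils::write.table(sites, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE,
                       fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a candidate-site or verdict table
#'
#' Inverse of [writeSitesTable()]; `#`-prefixed comment lines are ignored.
#'
#' @param path path to a TSV site table (1-based positions).
#' @return A `data.frame`.
#' @export
readSitesTable <- function(path) {
    if (!file.exists(path))
        stop("site table not found: ", path)
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (!length(lines))
        stop("site table is empty (no header): ", path)
    df <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE,
                            colClasses = NA, check.names = FALSE)
    if ("pos" %in% names(df)) df$pos <- as.integer(df$pos)
    df
}
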