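VAR_CLASSES <- c("SNP", "INS", "DEL")

classifyAllelePair <- function(ref, alt) {
  if (nchar(ref) == 1L && nchar(alt) == 1L) "SNP"
  else if (nchar(alt) > nchar(ref)) "INS"
  else if (nchar(ref) > nchar(alt)) "DEL"
  else NA_character_
}

#' Read inter-haplotype variants from a VCF
#'
#' Uses \pkg{vcfR} for parsing. Records are classified into SNP/INS/DEL by
#' allele length; multi-allelic records are split into one row per ALT allele.
#' Symbolic or otherwise unsupported alleles (e.g. \code{<DEL>}, breakends,
#' length-matched multi-nucleotide substitutions) are skipped with a message
#' reporting how many were dropped.
#'
#' @param path VCF file (v4.x subset: CHROM POS ID REF ALT).
#' @return data.frame with seq_name, pos (1-based), ref, alt, var_class.
#' @export
readVariants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(nrow(fix))) fix <- matrix(fix, nrow = 1L,
                                        dimnames = list(NULL, names(fix)))
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    ref <- fix[i, "REF"]
    for (alt in strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]) {
      if (grepl("[<>\\[\\]]", alt) || !grepl("^[ACGTN]+$", alt) ||
          !grepl("^[ACGTN]+$", ref)) {
        skipped <- skipped + 1L
        next
      }
      cls <- classifyAllelePair(ref, alt)
      if (is.na(cls)) {
        skipped <- skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        seq_name = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = ref, alt = alt, var_class = cls, stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0L)
    message("readVariants: skipped ", skipped, " unsupported allele record(s)")
  if (length(rows) == 0L)
    return(data.frame(seq_name = character(), pos = integer(),
                      ref = character(), alt = character(),
                      var_class = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write variants to a minimal VCF
#' @param variants data.frame as returned by \code{\link{readVariants}}.
#' @param path output file.
#' @export
writeVariants <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants)) {
    v <- variants[order(variants$seq_name, variants$pos,
                        seq_len(nrow(variants))), , drop = FALSE]
    writeLines(paste(v$seq_name, v$pos, ".", v$ref, v$alt, ".", "PASS", ".",
                     sep = "\t"), con)
  }
  invisible(path)
}

BLOCK_CLASSES <- c("SYN", "INV", "TRANS", "DUP", "NOTAL", "INS", "DEL")

#' Read synteny/structural blocks (SyRI-like TSV)
#'
#' Expected columns: ref_seq, ref_start, ref_end, qry_seq, qry_start, qry_end,
#' class (tab-separated, with header). Coordinates are 1-based inclusive;
#' \code{"-"} or empty marks a missing side (NOTAL records have coordinates on
#' exactly one side; INS/DEL records may carry an anchor point on the other
#' side). Orientation is derived from the class (INV = inverted).
#'
#' @param path TSV file.
#' @return data.frame of blocks with an added \code{orientation} column.
#' @export
readSynteny <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("ref_seq", "ref_start", "ref_end", "qry_seq", "qry_start",
            "qry_end", "class")
  if (!all(need %in% names(df)))
    stop("synteny table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$class), BLOCK_CLASSES)
  if (length(bad))
    stop("unknown block class '", bad[1L], "'; allowed classes are: ",
         paste(BLOCK_CLASSES, collapse = ", "))
  for (col in c("ref_start", "ref_end", "qry_start", "qry_end")) {
    df[[col]][df[[col]] %in% c("-", "")] <- NA
    df[[col]] <- as.integer(df[[col]])
  }
  df$ref_seq[df$ref_seq %in% c("-", "")] <- NA
  df$qry_seq[df$qry_seq %in% c("-", "")] <- NA
  hasRef <- !is.na(df$ref_start)
  hasQry <- !is.na(df$qry_start)
  if (any(df$class == "NOTAL" & hasRef & hasQry))
    stop("NOTAL blocks must have coordinates on exactly one side")
  if (any(hasRef & df$ref_end < df$ref_start) ||
      any(hasQry & df$qry_end < df$qry_start))
    stop("block end < start")
  df$orientation <- ifelse(df$class == "INV", "inverted", "same")
  df[, c(need, "orientation")]
}

#' Write synteny blocks
#' @param blocks data.frame of blocks.
#' @param path output TSV file.
#' @export
writeSynteny <- function(blocks, path) {
  out <- blocks[, c("ref_seq", "ref_start", "ref_end", "qry_seq",
                    "qry_start", "qry_end", "class")]
  for (col in names(out)) out[[col]][is.na(out[[col]])] <- "-"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

TE_CLASSES <- c("LTR", "TIR", "Helitron", "other")

#' Read a transposable-element track (BED)
#'
#' BED intervals (0-based half-open on disk) with the TE class in the name
#' column; unknown classes are mapped to \code{"other"}.
#'
#' @param path BED file.
#' @return data.frame with seq_name, start, end (1-based inclusive), te_class.
#' @export
readTeTrack <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  cls <- if (is.null(gr$name)) rep("other", length(gr)) else as.character(gr$name)
  cls[!cls %in% TE_CLASSES] <- "other"
  data.frame(seq_name = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             te_class = cls, stringsAsFactors = FALSE)
}

#' Write a transposable-element track (BED)
#' @param te data.frame with seq_name, start, end (1-based incl.), te_class.
#' @param path output BED file.
#' @export
writeTeTrack <- function(te, path) {
  writeLines(paste(te$seq_name, te$start - 1L, te$end, te$te_class,
                   sep = "\t"), path)
  invisible(path)
}

#' Read a per-tissue expression table
#'
#' TSV with a \code{gene_id} column followed by one numeric column per tissue.
#'
#' @param path TSV file.
#' @return numeric matrix (genes x tissues) with gene ids as rownames.
#' @export
readExpression <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "gene_id")
    stop("first column of an expression table must be gene_id")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in expression table")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  if (any(m < 0)) stop("expression table contains negative values")
  m
}

#' Write a per-tissue expression table
#' @param tpm numeric matrix, genes x tissues.
#' @param path output TSV file.
#' @export
writeExpression <- function(tpm, path) {
  df <- data.frame(gene_id = rownames(tpm), tpm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read splice-junction hints
#'
#' TSV of intron coordinates with columns seq_name, start, end (1-based
#' inclusive intron bounds), strand.
#'
#' @param path TSV file.
#' @return data.frame of hinted introns.
#' @export
readJunctions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("seq_name", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stop("junction table must have columns: ", paste(need, collapse = ", "))
  df[, need]
}

#' Write splice-junction hints
#' @param junctions data.frame with seq_name, start, end, strand.
#' @param path output TSV file.
#' @export
writeJunctions <- function(junctions, path) {
  write.table(junctions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
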