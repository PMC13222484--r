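#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features (via \pkg{rtracklayer}) and rebuilds the
#' gene -> transcript -> exon/CDS hierarchy from ID/Parent attributes. The
#' result does not depend on the order of lines in the file. External 1-based
#' inclusive coordinates are converted to the internal 0-based half-open
#' convention.
#'
#' @param path GFF3 file.
#' @param haplotype optional haplotype label attached to each gene.
#' @return named list of \linkS4class{GeneModel} (names = gene ids).
#' @export
readGff3 <- function(path, haplotype = NA_character_) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("failed to parse GFF3 '", path,
                                          "': ", conditionMessage(e)))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(modelList(list()))
  df$type <- as.character(df$type)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$Parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, character(1L))
  df$ID <- if (is.null(gr$ID)) NA_character_ else as.character(gr$ID)
  if (is.null(df$phase)) df$phase <- NA_integer_

  genes <- df[df$type == "gene", , drop = FALSE]
  rnas <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  parts <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (anyNA(rnas$Parent))
    stop("GFF3 parse error: mRNA feature without Parent (id ",
         paste(rnas$ID[is.na(rnas$Parent)], collapse = ","), ")")
  if (anyNA(parts$Parent))
    stop("GFF3 parse error: exon/CDS feature without Parent attribute")
  unknown <- setdiff(parts$Parent, rnas$ID)
  if (length(unknown))
    stop("GFF3 parse error: Parent '", unknown[1L],
         "' of an exon/CDS feature is not an annotated mRNA")

  out <- lapply(seq_len(nrow(genes)), function(gi) {
    gid <- genes$ID[gi]
    tx_rows <- rnas[rnas$Parent == gid, , drop = FALSE]
    if (nrow(tx_rows) == 0L)
      stop("GFF3 parse error: gene '", gid, "' has no mRNA children")
    txs <- lapply(seq_len(nrow(tx_rows)), function(ti) {
      tid <- tx_rows$ID[ti]
      p <- parts[parts$Parent == tid, , drop = FALSE]
      ex <- p[p$type == "exon", , drop = FALSE]
      cd <- p[p$type == "CDS", , drop = FALSE]
      if (nrow(ex) == 0L)
        stop("GFF3 parse error: mRNA '", tid, "' has no exons")
      transcriptModel(tid,
        exons = cbind(ex$start - 1L, ex$end),
        cds = if (nrow(cd)) cbind(cd$start - 1L, cd$end,
                                  ifelse(is.na(cd$phase), 0L,
                                         as.integer(as.character(cd$phase))))
              else NULL)
    })
    geneModel(gid, genes$seqnames[gi], genes$strand[gi], txs,
              sourceHaplotype = haplotype)
  })
  modelList(out)
}

#' Write gene models to a GFF3 file
#'
#' Emits 1-based inclusive coordinates in a deterministic order (sequence,
#' start, gene id); exon rows are always ascending by coordinate regardless of
#' strand.
#'
#' @param models named list of \linkS4class{GeneModel}.
#' @param path output file.
#' @param source value for the GFF3 source column.
#' @export
writeGff3 <- function(models, path, source = "haprefine") {
  ids <- vapply(models, geneId, character(1L))
  if (anyDuplicated(ids))
    stop("refusing to write duplicate gene ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(models) == 0L) return(invisible(path))
  sp <- modelSpans(models)
  ord <- order(sp$seq_name, sp$start, sp$gene_id)
  fmt <- function(seq, type, s0, e0, strand, phase, attrs)
    paste(seq, source, type, s0 + 1L, e0, ".", strand,
          phase, attrs, sep = "\t")
  for (i in ord) {
    g <- models[[i]]
    gsp <- geneSpan(g)
    writeLines(fmt(g@seqName, "gene", gsp[1L], gsp[2L], g@strand, ".",
                   paste0("ID=", g@geneId)), con)
    for (tx in g@transcripts) {
      tsp <- c(tx@exons[1L, 1L], max(tx@exons[, 2L]))
      writeLines(fmt(g@seqName, "mRNA", tsp[1L], tsp[2L], g@strand, ".",
                     paste0("ID=", tx@transcriptId, ";Parent=", g@geneId)), con)
      for (j in seq_len(nrow(tx@exons)))
        writeLines(fmt(g@seqName, "exon", tx@exons[j, 1L], tx@exons[j, 2L],
                       g@strand, ".",
                       paste0("ID=", tx@transcriptId, ".exon", j,
                              ";Parent=", tx@transcriptId)), con)
      for (j in seq_len(nrow(tx@cds)))
        writeLines(fmt(g@seqName, "CDS", tx@cds[j, 1L], tx@cds[j, 2L],
                       g@strand, tx@cds[j, 3L],
                       paste0("ID=", tx@transcriptId, ".cds;Parent=",
                              tx@transcriptId)), con)
    }
  }
  invisible(path)
}
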