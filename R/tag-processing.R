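#' @import data.table
NULL

## data.table NSE column names
utils::globalVariables(c(
  "tag", "count", "gene_id", "transcript_id", "pos", "strand", "n_genes",
  "unambiguous", "variant", "query", "status", "tier", ".N", "sense",
  "antisense", "J", "i.gene_id", "i.count", "qi", "dist", "hitkey"
))

#' Clean raw 35-nt reads into CATG+17 tags
#'
#' Each read is trimmed at the first occurrence of the 3' adaptor (its
#' leading 14 nt, the portion that fits in a 35-nt read), or truncated to
#' 21 nt when no adaptor is found.  A trimmed read is kept as a clean tag iff
#' it is exactly 21 nt, begins with CATG, and contains no N.  Rejections are
#' tallied by class: \code{empty_tag} (adaptor at position 1),
#' \code{bad_length}, \code{contains_n}, \code{no_catg_prefix}.
#'
#' @param reads character vector of reads (or a file read with
#'   \code{\link{readTagReads}}).
#' @param adaptor3 3' adaptor sequence (>= 14 nt).
#' @return a \linkS4class{CleanTagSet}.
#' @export
extractCleanTags <- function(reads, adaptor3 = DEFAULT_ADAPTOR3) {
  raw_total <- length(reads)
  report <- c(empty_tag = 0, bad_length = 0, contains_n = 0,
              no_catg_prefix = 0)
  if (!raw_total) {
    return(methods::new("CleanTagSet",
      tags = data.frame(tag = character(), count = integer()),
      rawTotal = 0, cleanTotal = 0, report = report))
  }
  fill <- substr(adaptor3, 1L, 14L)
  hit <- regexpr(fill, reads, fixed = TRUE)
  tagseq <- ifelse(hit > 0L, substr(reads, 1L, hit - 1L),
                   substr(reads, 1L, 21L))
  empty <- hit == 1L
  badlen <- !empty & nchar(tagseq) != 21L
  hasn <- !empty & !badlen & grepl("[^ACGT]", tagseq)
  nocatg <- !empty & !badlen & !hasn & !startsWith(tagseq, "CATG")
  keep <- !(empty | badlen | hasn | nocatg)
  report["empty_tag"] <- sum(empty)
  report["bad_length"] <- sum(badlen)
  report["contains_n"] <- sum(hasn)
  report["no_catg_prefix"] <- sum(nocatg)
  dt <- data.table(tag = tagseq[keep])[, .(count = .N), by = tag]
  setorder(dt, tag)
  methods::new("CleanTagSet",
    tags = as.data.frame(dt), rawTotal = raw_total,
    cleanTotal = sum(dt$count), report = report)
}

#' Build the virtual CATG+17 tag library from a reference transcriptome
#'
#' Scans every transcript on both strands (the antisense entries come from
#' the reverse complement) and indexes each CATG occurrence followed by at
#' least 17 nt as one 21-mer key.  Positions are 0-based starts of the CATG
#' on the indexed strand's sequence.
#'
#' @param transcripts a named \link[Biostrings]{DNAStringSet} or the path of
#'   a FASTA file.
#' @param geneMap data.frame with columns \code{gene_id},
#'   \code{transcript_id}; every transcript must be listed.
#' @return a \linkS4class{TagLibrary}.
#' @export
buildVirtualLibrary <- function(transcripts, geneMap) {
  if (is.character(transcripts)) {
    transcripts <- Biostrings::readDNAStringSet(transcripts)
    names(transcripts) <- sub("\\s.*$", "", names(transcripts))
  }
  ids <- names(transcripts)
  miss <- setdiff(ids, geneMap$transcript_id)
  if (length(miss)) {
    stop("transcript(s) missing from gene map: ",
         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  }
  gene_of <- geneMap$gene_id[match(ids, geneMap$transcript_id)]
  scanStrand <- function(seqs, strand) {
    chars <- as.character(seqs)
    sites <- gregexpr("CATG", chars, fixed = TRUE)
    lens <- nchar(chars)
    rows <- lapply(seq_along(chars), function(i) {
      p <- sites[[i]]
      p <- p[p > 0 & p + 20L <= lens[i]]
      if (!length(p)) return(NULL)
      data.table(tag = substring(chars[i], p, p + 20L),
                 gene_id = gene_of[i], transcript_id = ids[i],
                 pos = p - 1L, strand = strand)
    })
    rbindlist(rows)
  }
  hits <- rbind(
    scanStrand(transcripts, "sense"),
    scanStrand(Biostrings::reverseComplement(transcripts), "antisense")
  )
  if (!nrow(hits)) {
    return(methods::new("TagLibrary",
      hits = data.frame(tag = character(), gene_id = character(),
                        transcript_id = character(), pos = integer(),
                        strand = character()),
      tagInfo = data.frame(tag = character(), n_genes = integer(),
                           unambiguous = logical(), gene_id = character(),
                           sense = logical(), antisense = logical())))
  }
  setorder(hits, tag, gene_id, transcript_id, pos, strand)
  info <- hits[, .(n_genes = uniqueN(gene_id),
                   gene_id = if (uniqueN(gene_id) == 1L) gene_id[1]
                             else NA_character_,
                   sense = if (uniqueN(gene_id) == 1L) any(strand == "sense")
                           else NA,
                   antisense = if (uniqueN(gene_id) == 1L)
                     any(strand == "antisense") else NA),
               by = tag]
  info[, unambiguous := n_genes == 1L]
  setcolorder(info, c("tag", "n_genes", "unambiguous", "gene_id",
                      "sense", "antisense"))
  methods::new("TagLibrary", hits = as.data.frame(hits),
               tagInfo = as.data.frame(info))
}

## All Hamming-distance-1 neighbours of the query tags.  Both clean tags and
## library keys begin with CATG, so a single mismatch can only sit in
## positions 5..21; queries without the CATG prefix get all 21 positions.
mismatchNeighbours <- function(tags) {
  positions <- function(tg, pos_range) {
    out <- vector("list", length(pos_range) * 3L)
    k <- 0L
    for (p in pos_range) {
      orig <- substr(tg, p, p)
      for (b in DNA_BASES) {
        vr <- tg
        substr(vr, p, p) <- b
        sel <- b != orig
        if (any(sel)) {
          k <- k + 1L
          out[[k]] <- data.table(query = tg[sel], variant = vr[sel])
        }
      }
    }
    rbindlist(out[seq_len(k)])
  }
  catg <- startsWith(tags, "CATG")
  rbind(
    if (any(catg)) positions(tags[catg], 5:21) else NULL,
    if (any(!catg)) positions(tags[!catg], 1:21) else NULL
  )
}

#' Map clean tags to the virtual library with up to one mismatch
#'
#' Tier 1 is an exact key lookup; only tags with no exact hit proceed to
#' tier 2, which considers every library key at Hamming distance 1.  The
#' union of genes hit at the accepted tier decides the tag's fate: one gene
#' makes it unambiguous (counted, with strand recorded), several make it
#' ambiguous (mapped but excluded from gene counts), none leaves it unknown.
#' Gene expression counts sum the copy numbers of sense-strand unambiguous
#' tags; antisense unambiguous tags are tallied separately for the strand
#' report.
#'
#' @param tags a \linkS4class{CleanTagSet}.
#' @param library a \linkS4class{TagLibrary}.
#' @param maxMismatch 0 or 1.
#' @return list with \code{assignments} (per distinct tag: \code{tag},
#'   \code{count}, \code{tier}, \code{status}, \code{gene_id},
#'   \code{strand}), \code{geneCounts} (per gene: sense/antisense/total
#'   unambiguous tag counts and distinct-tag counts) and \code{summary}
#'   (total and distinct tag accounting by mapping class).
#' @export
mapTags <- function(tags, library, maxMismatch = 1) {
  if (!maxMismatch %in% c(0L, 1L)) {
    stop("'maxMismatch' must be 0 or 1", call. = FALSE)
  }
  qry <- as.data.table(tagCounts(tags))
  info <- as.data.table(library@tagInfo)
  pairs <- unique(as.data.table(library@hits)[, .(tag, gene_id, strand)])
  res <- data.table(tag = character(), count = integer(), tier = integer(),
                    status = character(), gene_id = character(),
                    strand = character())
  if (nrow(qry)) {
    m <- match(qry$tag, info$tag)
    exact <- !is.na(m)
    if (any(exact)) {
      ei <- info[m[exact]]
      res <- rbind(res, data.table(
        tag = qry$tag[exact], count = qry$count[exact], tier = 0L,
        status = ifelse(ei$unambiguous, "unambiguous", "ambiguous"),
        gene_id = ei$gene_id,
        strand = ifelse(!ei$unambiguous, NA_character_,
                        ifelse(ei$sense & ei$antisense, "both",
                               ifelse(ei$sense, "sense", "antisense")))))
    }
    rest <- qry[!exact]
    if (nrow(rest) && maxMismatch >= 1L) {
      nb <- mismatchNeighbours(rest$tag)
      setkey(pairs, tag)
      hits2 <- pairs[nb, on = c(tag = "variant"), nomatch = NULL,
                     .(query, gene_id, strand)]
      if (nrow(hits2)) {
        agg <- hits2[, .(
          n_genes = uniqueN(gene_id),
          gene_id = if (uniqueN(gene_id) == 1L) gene_id[1] else NA_character_,
          sense = any(strand == "sense"),
          antisense = any(strand == "antisense")), by = query]
        agg <- agg[rest, on = c(query = "tag"), nomatch = NULL]
        res <- rbind(res, data.table(
          tag = agg$query, count = agg$count, tier = 1L,
          status = ifelse(agg$n_genes == 1L, "unambiguous", "ambiguous"),
          gene_id = agg$gene_id,
          strand = ifelse(agg$n_genes > 1L, NA_character_,
                          ifelse(agg$sense & agg$antisense, "both",
                                 ifelse(agg$sense, "sense", "antisense")))))
        rest <- rest[!agg$query, on = "tag"]
      }
    }
    if (nrow(rest)) {
      res <- rbind(res, data.table(
        tag = rest$tag, count = rest$count, tier = NA_integer_,
        status = "unknown", gene_id = NA_character_,
        strand = NA_character_))
    }
  }
  setorder(res, tag)
  unamb <- res[status == "unambiguous"]
  geneCounts <- unamb[, .(
    count_sense = sum(count[strand %in% c("sense", "both")]),
    count_antisense = sum(count[strand %in% c("antisense", "both")]),
    count_all = sum(count),
    distinct_sense = sum(strand %in% c("sense", "both")),
    distinct_antisense = sum(strand %in% c("antisense", "both")),
    distinct_all = .N), by = gene_id]
  setorder(geneCounts, gene_id)
  tot <- function(sel) c(total = sum(res$count[sel]), distinct = sum(sel))
  summary <- rbind(
    clean = c(total = cleanTotal(tags), distinct = nrow(res)),
    all_mapped = tot(res$status != "unknown"),
    unambiguous = tot(res$status == "unambiguous"),
    ambiguous = tot(res$status == "ambiguous"),
    unknown = tot(res$status == "unknown"))
  list(assignments = as.data.frame(res),
       geneCounts = as.data.frame(geneCounts),
       summary = as.data.frame(summary))
}

#' Exhaustive reference mapper (all-pairs Hamming scan)
#'
#' Brute-force counterpart of \code{\link{mapTags}}: compares every query
#' tag against every library key, applies the same tier rule (exact hits
#' before distance-1 hits) and ambiguity rule, and returns per-tag
#' assignments.  Quadratic; intended as an independent check of the
#' production mapper on moderate inputs.
#'
#' @inheritParams mapTags
#' @return data.frame like the \code{assignments} element of
#'   \code{\link{mapTags}}.
#' @export
bruteForceMapTags <- function(tags, library, maxMismatch = 1) {
  qry <- tagCounts(tags)
  pairs <- unique(library@hits[, c("tag", "gene_id", "strand")])
  keys <- unique(pairs$tag)
  hh <- cpp_all_pairs_hamming(qry$tag, keys, as.integer(maxMismatch))
  hitdt <- data.table(qi = hh$query, hitkey = keys[hh$key], dist = hh$dist)
  pairsdt <- as.data.table(pairs)
  out <- lapply(seq_len(nrow(qry)), function(i) {
    d <- hitdt[qi == i]
    if (!nrow(d)) {
      return(data.frame(tag = qry$tag[i], count = qry$count[i],
                        tier = NA_integer_, status = "unknown",
                        gene_id = NA_character_, strand = NA_character_,
                        stringsAsFactors = FALSE))
    }
    tierOf <- min(d$dist)
    ph <- pairsdt[tag %in% d$hitkey[d$dist == tierOf]]
    gg <- unique(ph$gene_id)
    if (length(gg) == 1L) {
      sn <- any(ph$strand == "sense")
      as_ <- any(ph$strand == "antisense")
      data.frame(tag = qry$tag[i], count = qry$count[i], tier = tierOf,
                 status = "unambiguous", gene_id = gg,
                 strand = if (sn && as_) "both" else if (sn) "sense"
                          else "antisense", stringsAsFactors = FALSE)
    } else {
      data.frame(tag = qry$tag[i], count = qry$count[i], tier = tierOf,
                 status = "ambiguous", gene_id = NA_character_,
                 strand = NA_character_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  out[order(out$tag), , drop = FALSE]
}
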