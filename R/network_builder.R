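#' Build a relevance network by thresholding a correlation matrix
#'
#' Links every defined pair of entities whose correlation is at least `t`
#' (inclusive). Self-pairs are never edges; entities with no edge are not
#' nodes.
#'
#' @param corr a `correlation_result`.
#' @param t correlation threshold.
#' @return Object of class `relevance_network`: `edges` (data.frame
#'   `entity_i`, `entity_j`, `r`, with i < j lexicographically within the
#'   entity order and deterministic row order), `nodes`, `threshold`,
#'   `method`.
#' @export
build_network <- function(corr, t) {
  stopifnot(inherits(corr, "correlation_result"))
  pairs <- correlation_pairs(corr)
  edges <- pairs[pairs$r >= t, , drop = FALSE]
  edges <- edges[order(edges$entity_i, edges$entity_j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$entity_i, edges$entity_j))),
                 threshold = t, method = corr$method),
            class = "relevance_network")
}

#' @export
print.relevance_network <- function(x, ...) {
  cat(sprintf("relevance_network (%s, t = %g): %d nodes, %d links\n",
              x$method, x$threshold, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Threshold matching a target link count
#'
#' Finds the largest threshold `t` at which the network has at least
#' `target_links` edges (an exact match can be impossible under ties), used
#' to equalize link counts when comparing two methods.
#'
#' @param corr a `correlation_result`.
#' @param target_links desired number of links (>= 1, <= defined pairs).
#' @return list with `threshold` and `achieved` (the realized link count).
#' @export
match_link_count <- function(corr, target_links) {
  stopifnot(inherits(corr, "correlation_result"))
  r <- sort(correlation_pairs(corr)$r, decreasing = TRUE)
  if (target_links < 1 || target_links > length(r))
    stop("target_links must be between 1 and the number of defined pairs (",
         length(r), ")")
  t <- r[target_links]
  list(threshold = t, achieved = sum(r >= t))
}

#' Difference between two relevance networks
#'
#' Labels the union of edges as `shared`, `A_only` or `B_only`, and every
#' incident node as `shared` (has at least one edge in both networks),
#' `A_only` or `B_only`.
#'
#' @param netA,netB [build_network()] results on the same entity universe.
#' @return list with `edges` (data.frame `entity_i`, `entity_j`, `status`)
#'   and `nodes` (data.frame `entity`, `status`).
#' @export
difference_network <- function(netA, netB) {
  keyA <- paste(netA$edges$entity_i, netA$edges$entity_j, sep = "\r")
  keyB <- paste(netB$edges$entity_i, netB$edges$entity_j, sep = "\r")
  all_keys <- sort(union(keyA, keyB))
  status <- ifelse(all_keys %in% keyA & all_keys %in% keyB, "shared",
                   ifelse(all_keys %in% keyA, "A_only", "B_only"))
  parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  edges <- data.frame(entity_i = parts[, 1L], entity_j = parts[, 2L],
                      status = status)
  all_nodes <- sort(union(netA$nodes, netB$nodes))
  node_status <- ifelse(all_nodes %in% netA$nodes & all_nodes %in% netB$nodes,
                        "shared",
                        ifelse(all_nodes %in% netA$nodes, "A_only", "B_only"))
  list(edges = edges, nodes = data.frame(entity = all_nodes,
                                         status = node_status))
}

#' Parse miRBase GFF3 definitions
#'
#' Extracts, from a miRBase `hsa.gff3`-style file, (i) the map from mature
#' miRNA accessions (the `Alias` attribute, which omits the `_1`/`_2`
#' multi-locus suffixes of the `ID` field) to their stem-loop precursor ids,
#' and (ii) the genomic intervals of every mature occurrence.
#'
#' @param path path to the GFF3 file.
#' @return list with `stemloop_map` (data.frame `mature_id`, `stemloop_id`)
#'   and `mature_loci` (data.frame `mature_id`, `chrom`, `start`, `end`; one
#'   row per genomic occurrence).
#' @export
read_mirbase_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  is_mat <- type == "miRNA"
  is_pre <- type %in% c("miRNA_primary_transcript", "miRNA_stem_loop")
  alias <- vapply(meta$Alias, function(a)
    if (length(a)) as.character(a[[1L]]) else NA_character_, character(1))
  id <- as.character(meta$ID)
  derives <- if ("Derives_from" %in% names(meta))
    as.character(meta$Derives_from) else rep(NA_character_, length(gr))
  # stem-loop id for a mature record: resolve Derives_from to the precursor
  # Alias (stable accession), falling back to its ID
  pre_alias <- stats::setNames(ifelse(is.na(alias[is_pre]), id[is_pre],
                                      alias[is_pre]), id[is_pre])
  mat <- which(is_mat)
  stemloop_map <- data.frame(
    mature_id = ifelse(is.na(alias[mat]), id[mat], alias[mat]),
    stemloop_id = unname(pre_alias[derives[mat]]))
  stemloop_map <- unique(stemloop_map[!is.na(stemloop_map$stemloop_id), ])
  mature_loci <- data.frame(
    mature_id = ifelse(is.na(alias[mat]), id[mat], alias[mat]),
    chrom = as.character(GenomicRanges::seqnames(gr))[mat],
    start = GenomicRanges::start(gr)[mat],
    end = GenomicRanges::end(gr)[mat])
  list(stemloop_map = stemloop_map, mature_loci = mature_loci)
}

#' Parse transcript intervals from an ENSEMBL GTF
#'
#' @param path path to the GTF file.
#' @return data.frame `transcript_id`, `chrom`, `start`, `end` over records
#'   of type `transcript`.
#' @export
read_transcript_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[as.character(S4Vectors::mcols(gr)$type) == "transcript"]
  data.frame(transcript_id = as.character(S4Vectors::mcols(gr)$transcript_id),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr))
}

#' Genomic-locality categories for network edges
#'
#' Assigns each edge the first applicable category, testing all genomic
#' occurrences of both partners: (1) `stem-loop` — the partners share a
#' stem-loop precursor anywhere in the genome; (2) `transcript` — some
#' occurrence of each partner overlaps the same transcribed entity;
#' (3) `near` — some occurrence pair lies on the same chromosome within
#' 10 kb (closest-endpoint gap, 0 when overlapping); (4) `cluster` — the
#' partners fall in the same connected component of the transitive closure
#' of the `near` relation without being near themselves; (5) `non-local`.
#' Entities with no genomic record are `non-local` with a warning.
#'
#' @param net a [build_network()] result.
#' @param stemloop_map data.frame `mature_id`, `stemloop_id`.
#' @param mature_loci data.frame `mature_id`, `chrom`, `start`, `end` (one
#'   row per genomic occurrence; 1-based inclusive coordinates).
#' @param transcript_loci optional data.frame `transcript_id`, `chrom`,
#'   `start`, `end`; when `NULL` the `transcript` category is never assigned.
#' @param near_bp distance defining `near` (default 10000).
#' @return factor of length `nrow(net$edges)` with levels `stem-loop`,
#'   `transcript`, `near`, `cluster`, `non-local`.
#' @export
annotate_locality <- function(net, stemloop_map, mature_loci,
                              transcript_loci = NULL, near_bp = 10000) {
  stopifnot(inherits(net, "relevance_network"))
  lv <- c("stem-loop", "transcript", "near", "cluster", "non-local")
  edges <- net$edges
  if (nrow(edges) == 0L)
    return(factor(character(0), levels = lv))
  no_record <- setdiff(net$nodes, mature_loci$mature_id)
  if (length(no_record))
    warning("no genomic record for: ", paste(no_record, collapse = ", "),
            "; incident edges fall back to non-local")
  stemloops <- split(stemloop_map$stemloop_id, stemloop_map$mature_id)
  occ_gr <- GenomicRanges::GRanges(
    mature_loci$chrom,
    IRanges::IRanges(mature_loci$start, mature_loci$end))
  occ_of <- split(seq_len(nrow(mature_loci)), mature_loci$mature_id)
  if (!is.null(transcript_loci)) {
    tx_gr <- GenomicRanges::GRanges(
      transcript_loci$chrom,
      IRanges::IRanges(transcript_loci$start, transcript_loci$end))
    ov <- GenomicRanges::findOverlaps(occ_gr, tx_gr)
    tx_of_occ <- split(transcript_loci$transcript_id[S4Vectors::subjectHits(ov)],
                       factor(S4Vectors::queryHits(ov),
                              levels = seq_along(occ_gr)))
  }
  # near graph over occurrences: same chromosome, gap <= near_bp
  near_hits <- GenomicRanges::findOverlaps(occ_gr, maxgap = near_bp,
                                           drop.self = TRUE,
                                           drop.redundant = TRUE)
  g <- igraph::graph_from_edgelist(
    cbind(S4Vectors::queryHits(near_hits), S4Vectors::subjectHits(near_hits)),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(occ_gr) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership

  is_near <- function(a, b) {
    oa <- occ_of[[a]]; ob <- occ_of[[b]]
    if (is.null(oa) || is.null(ob)) return(FALSE)
    any(!is.na(GenomicRanges::distance(
      occ_gr[rep(oa, each = length(ob))],
      occ_gr[rep(ob, times = length(oa))])) &
      GenomicRanges::distance(
        occ_gr[rep(oa, each = length(ob))],
        occ_gr[rep(ob, times = length(oa))]) <= near_bp)
  }
  category <- character(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    a <- edges$entity_i[e]; b <- edges$entity_j[e]
    if (length(intersect(stemloops[[a]], stemloops[[b]])) > 0) {
      category[e] <- "stem-loop"
    } else if (!is.null(transcript_loci) &&
               length(intersect(
                 unlist(tx_of_occ[as.character(occ_of[[a]])]),
                 unlist(tx_of_occ[as.character(occ_of[[b]])]))) > 0) {
      category[e] <- "transcript"
    } else if (is_near(a, b)) {
      category[e] <- "near"
    } else if (!is.null(occ_of[[a]]) && !is.null(occ_of[[b]]) &&
               length(intersect(comp[occ_of[[a]]], comp[occ_of[[b]]])) > 0) {
      category[e] <- "cluster"
    } else {
      category[e] <- "non-local"
    }
  }
  factor(category, levels = lv)
}

#' Export a relevance network
#'
#' Formats: `sif` (`idA<TAB>relation<TAB>idB`, relation `co` plus the
#' locality category when supplied), `graphml` (via igraph, with `r` and
#' optional `locality` edge attributes) and `tsv` (long edge list).
#' Edge order is deterministic (entity_i, then entity_j, lexicographic).
#'
#' @param net a [build_network()] result.
#' @param path output path.
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @param annotation optional [annotate_locality()] factor aligned to
#'   `net$edges`.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "tsv"),
                           annotation = NULL) {
  stopifnot(inherits(net, "relevance_network"))
  format <- match.arg(format)
  edges <- net$edges
  if (!is.null(annotation)) {
    stopifnot(length(annotation) == nrow(edges))
    edges$locality <- as.character(annotation)
  }
  if (format == "sif") {
    rel <- if (is.null(annotation)) rep("co", nrow(edges)) else edges$locality
    writeLines(if (nrow(edges)) paste(edges$entity_i, rel, edges$entity_j,
                                      sep = "\t") else character(0), path)
  } else if (format == "tsv") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = net$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
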