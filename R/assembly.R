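# Genome-guided splice-graph assembly of one bin's coordinate-sorted
# alignment records.
#
# The reference algorithm is deliberately exact rather than heuristic:
# exon fragments are maximal covered intervals split at junction
# boundaries, the splice graph connects fragments through junctions, and
# transcripts are all maximal paths per connected component enumerated
# in a deterministic leftmost-first order. No parity with StringTie or
# Scallop internals is claimed; external assemblers plug in through
# [assembler_adapter()].

#' Assembly parameters
#'
#' @param min_cov minimum mean per-base coverage for an exon fragment to
#'   enter the splice graph (default 1.0). Fragment candidates are
#'   maximal intervals of non-zero coverage; with the default, the
#'   per-base and mean thresholds coincide for integer coverage.
#' @param min_junction_support minimum number of spliced reads required
#'   for a junction to contribute an edge (default 1).
#' @param max_paths_per_component cap on enumerated maximal paths per
#'   connected component; exceeding it truncates the component with a
#'   warning, never a silent reordering (default 64).
#' @return object of class `assembly_params`.
#' @export
assembly_params <- function(min_cov = 1.0, min_junction_support = 1L,
                            max_paths_per_component = 64L) {
  check(min_cov > 0 && min_junction_support >= 1 && max_paths_per_component >= 1,
        "assembly parameters must be positive")
  structure(list(min_cov = min_cov,
                 min_junction_support = as.integer(min_junction_support),
                 max_paths_per_component = as.integer(max_paths_per_component)),
            class = "assembly_params")
}

#' Filter an annotation to the chromosome of a bin
#'
#' The partial annotation handed to guided assembly: exactly the
#' transcripts on the bin's chromosome.
#'
#' @param annotation a `transcript_set`.
#' @param bin a bin name `"chrom:index"`.
#' @return a `transcript_set`.
#' @export
filter_annotation_for_bin <- function(annotation, bin) {
  chrom <- strsplit(bin, ":", fixed = TRUE)[[1]][1]
  annotation[annotation$chrom == chrom, , drop = FALSE]
}

#' Extract coverage and junction evidence from sorted records
#'
#' Per-base coverage counts aligned (M) segments only; every N CIGAR
#' operation contributes one junction occurrence. Junction strand is
#' read from the genomic splice motif: `GT..AG` is `+`, `CT..AC` is `-`,
#' anything else unknown (`.`).
#'
#' @param records coordinate-sorted mapped record data.frame, all on one
#'   chromosome.
#' @param genome named character vector of chromosome sequences (or
#'   FASTA path / DNAStringSet).
#' @return list with `chrom`, `coverage` (an [S4Vectors::Rle] over the
#'   whole chromosome) and `junctions` (data.frame `start`, `end`
#'   1-based inclusive intron coordinates, `support`, `strand`).
#' @export
extract_evidence <- function(records, genome) {
  genome <- as_genome(genome)
  no_junctions <- data.frame(start = integer(0), end = integer(0),
                             support = integer(0), strand = character(0),
                             stringsAsFactors = FALSE)
  if (nrow(records) == 0L) {
    return(list(chrom = NA_character_,
                coverage = S4Vectors::Rle(0L, 0L), junctions = no_junctions))
  }
  chroms <- unique(records$chrom)
  check(length(chroms) == 1L && !anyNA(chroms),
        "extract_evidence expects mapped records on a single chromosome, got: %s",
        paste(chroms, collapse = ", "))
  chrom <- chroms
  check(chrom %in% names(genome), "chromosome %s absent from genome", chrom)
  L <- nchar(genome[[chrom]])

  # vectorized CIGAR walk over all records at once
  ml <- gregexpr("(\\d+)([MIDNSHP=X])", records$cigar, perl = TRUE)
  toks <- regmatches(records$cigar, ml)
  ntok <- lengths(toks)
  check(all(ntok > 0L), "malformed CIGAR among bin records")
  toks <- unlist(toks, use.names = FALSE)
  op <- substring(toks, nchar(toks), nchar(toks))
  len <- as.integer(substring(toks, 1L, nchar(toks) - 1L))
  rec <- rep.int(seq_len(nrow(records)), ntok)
  consumes_ref <- op %in% c("M", "=", "X", "D", "N")
  ref_len <- ifelse(consumes_ref, len, 0L)
  cum <- cumsum(ref_len)
  group_end <- cumsum(ntok)
  group_base <- rep.int(c(0L, cum[group_end][-length(group_end)]), ntok)
  offset_before <- cum - ref_len - group_base   # ref consumed before this op
  start <- records$pos[rec] + offset_before
  is_m <- op %in% c("M", "=", "X")
  is_n <- op == "N"
  m_starts <- start[is_m]; m_ends <- start[is_m] + len[is_m] - 1L
  j_starts <- start[is_n]; j_ends <- start[is_n] + len[is_n] - 1L
  check(all(m_ends <= L) && all(j_ends <= L),
        "alignment extends past the end of chromosome %s (length %d)", chrom, L)
  cov <- IRanges::coverage(IRanges::IRanges(m_starts, m_ends), width = L)
  if (length(j_starts)) {
    key <- paste(j_starts, j_ends, sep = "-")
    tab <- table(key)
    uk <- names(tab)
    us <- as.integer(sub("-.*", "", uk))
    ue <- as.integer(sub(".*-", "", uk))
    o <- order(us, ue)
    us <- us[o]; ue <- ue[o]
    donor <- substring(genome[[chrom]], us, us + 1L)
    accep <- substring(genome[[chrom]], ue - 1L, ue)
    strand <- ifelse(donor == "GT" & accep == "AG", "+",
                     ifelse(donor == "CT" & accep == "AC", "-", "."))
    junctions <- data.frame(start = us, end = ue,
                            support = as.integer(tab[uk[o]]),
                            strand = strand, stringsAsFactors = FALSE)
  } else {
    junctions <- no_junctions
  }
  list(chrom = chrom, coverage = cov, junctions = junctions)
}

# Maximal covered intervals split at qualifying junction boundaries.
# Returns data.frame(start, end, mean_cov), 1-based inclusive.
exon_fragments <- function(coverage, junctions, min_cov) {
  covered <- IRanges::slice(coverage, lower = 1L, rangesOnly = TRUE)
  if (length(covered) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      mean_cov = numeric(0)))
  }
  # cut after position d-1 (donor d starts an intron) and after position a
  # (intron ends at a): boundaries expressed as "last position of left part"
  cuts <- sort(unique(c(junctions$start - 1L, junctions$end)))
  starts <- IRanges::start(covered); ends <- IRanges::end(covered)
  frag_s <- integer(0); frag_e <- integer(0)
  for (i in seq_along(starts)) {
    inner <- cuts[cuts >= starts[i] & cuts < ends[i]]
    bnd <- c(starts[i] - 1L, inner, ends[i])
    frag_s <- c(frag_s, utils::head(bnd, -1L) + 1L)
    frag_e <- c(frag_e, bnd[-1L])
  }
  v <- as.integer(coverage)
  mean_cov <- vapply(seq_along(frag_s), function(i)
    mean(v[frag_s[i]:frag_e[i]]), numeric(1))
  keep <- mean_cov >= min_cov
  data.frame(start = frag_s[keep], end = frag_e[keep],
             mean_cov = mean_cov[keep])
}

# All maximal paths through a DAG given by an adjacency list, leftmost
# (lowest node index) first, capped at max_paths. Nodes with no incident
# edge are excluded (they become single-exon transcripts elsewhere).
enumerate_paths <- function(n_nodes, edges_from, edges_to, max_paths) {
  adj <- lapply(seq_len(n_nodes), function(i) sort(edges_to[edges_from == i]))
  has_in <- tabulate(edges_to, n_nodes) > 0L
  has_out <- tabulate(edges_from, n_nodes) > 0L
  touched <- has_in | has_out
  # connected components over the undirected skeleton
  comp <- seq_len(n_nodes)
  repeat {
    new <- comp
    for (e in seq_along(edges_from)) {
      m <- min(new[edges_from[e]], new[edges_to[e]])
      new[edges_from[e]] <- m; new[edges_to[e]] <- m
    }
    if (identical(new, comp)) break
    comp <- new
  }
  sources <- which(touched & !has_in)
  paths_by_comp <- list()
  truncated <- character(0)
  for (cid in sort(unique(comp[touched]))) {
    paths <- list()
    capped <- FALSE
    dfs <- function(node, path) {
      if (capped) return()
      nxt <- adj[[node]]
      if (!length(nxt)) {
        if (length(paths) >= max_paths) { capped <<- TRUE; return() }
        paths[[length(paths) + 1L]] <<- path
        return()
      }
      for (m in nxt) dfs(m, c(path, m))
    }
    for (s in sources[comp[sources] == cid]) dfs(s, s)
    if (capped) truncated <- c(truncated, as.character(cid))
    paths_by_comp[[as.character(cid)]] <- paths
  }
  if (length(truncated)) {
    warning(sprintf("path enumeration capped at %d in %d component(s); output truncated",
                    max_paths, length(truncated)), call. = FALSE)
  }
  list(paths_by_comp = paths_by_comp, comp = comp, touched = touched)
}

#' Assemble transcripts for one bin
#'
#' De novo mode builds the splice graph from the bin's evidence and
#' emits every maximal path as a transcript (exon boundaries are
#' evidence-bounded: first/last covered base), plus single-exon
#' transcripts for isolated covered fragments with no incident
#' junctions. Guided mode first emits, verbatim, each partial-annotation
#' transcript whose introns are all present in the junction set (with
#' the required support), then de novo paths whose intron chain does not
#' duplicate an emitted reference chain. One gene is reported per
#' connected component.
#'
#' @param records coordinate-sorted stripped records of one bin (single
#'   chromosome).
#' @param genome genome sequences (named character vector, DNAStringSet
#'   or FASTA path).
#' @param params an [assembly_params()].
#' @param partial_annotation optional `transcript_set` already filtered
#'   with [filter_annotation_for_bin()]; enables guided mode.
#' @param bin bin name recorded in the output's `origin_bin` field.
#' @param bin_span optional 0-based half-open genomic interval
#'   `c(start, end)` of the bin. When given, de novo transcripts not
#'   fully contained in the bin are suppressed: their evidence leaks in
#'   from records that merely overlap the bin, and the bin-overlap
#'   geometry guarantees that the bin fully containing such a transcript
#'   reports the complete version, so suppression removes left/right
#'   truncated partials without losing any structure. Verbatim
#'   reference emissions are not filtered (identical across bins, so
#'   downstream deduplication collapses them).
#' @return a `transcript_set`.
#' @export
assemble_bin <- function(records, genome, params = assembly_params(),
                         partial_annotation = NULL, bin = NA_character_,
                         bin_span = NULL) {
  ev <- extract_evidence(records, genome)
  if (nrow(records) == 0L) return(empty_transcript_set())
  chrom <- ev$chrom
  jn <- ev$junctions
  jn_ok <- jn[jn$support >= params$min_junction_support, , drop = FALSE]
  frags <- exon_fragments(ev$coverage, jn_ok, params$min_cov)
  prefix <- if (is.na(bin)) chrom else gsub(":", ".", bin, fixed = TRUE)

  out <- list()
  ref_chains <- character(0)
  if (!is.null(partial_annotation) && nrow(partial_annotation)) {
    pa <- partial_annotation[partial_annotation$chrom == chrom, , drop = FALSE]
    jkey <- paste(jn_ok$start, jn_ok$end, sep = "-")
    supported <- vapply(seq_len(nrow(pa)), function(i) {
      intr <- exon_introns(pa$exons[[i]])
      nrow(intr) > 0L && all(paste(intr[, 1L], intr[, 2L], sep = "-") %in% jkey)
    }, logical(1))
    if (any(supported)) {
      emitted <- pa[supported, , drop = FALSE]
      emitted$source <- "reference"
      emitted$origin_bin <- bin
      out[[length(out) + 1L]] <- emitted
      ref_chains <- chain_key(emitted)
    }
  }

  if (nrow(frags)) {
    # junction edges between fragments abutting the intron's two ends
    nfrag <- nrow(frags)
    e_from <- integer(0); e_to <- integer(0); e_strand <- character(0)
    if (nrow(jn_ok)) {
      from <- match(jn_ok$start - 1L, frags$end)
      to <- match(jn_ok$end + 1L, frags$start)
      keep <- !is.na(from) & !is.na(to)
      e_from <- from[keep]; e_to <- to[keep]; e_strand <- jn_ok$strand[keep]
    }
    pe <- enumerate_paths(nfrag, e_from, e_to, params$max_paths_per_component)
    # deterministic gene numbering: components by leftmost fragment
    comp_ids <- sort(unique(pe$comp[pe$touched]))
    iso_frags <- which(!pe$touched)
    all_units <- c(lapply(comp_ids, function(cid) list(type = "comp", id = cid,
                                                      left = min(frags$start[pe$comp == cid & pe$touched]))),
                   lapply(iso_frags, function(fi) list(type = "frag", id = fi,
                                                      left = frags$start[fi])))
    if (length(all_units)) {
      all_units <- all_units[order(vapply(all_units, `[[`, numeric(1), "left"))]
      gnum <- 0L
      for (unit in all_units) {
        gnum <- gnum + 1L
        gene_id <- sprintf("%s.g%d", prefix, gnum)
        if (unit$type == "frag") {
          fi <- unit$id
          out[[length(out) + 1L]] <- transcript_set(
            transcript_id = sprintf("%s.t1", gene_id), gene_id = gene_id,
            chrom = chrom, strand = ".",
            exons = list(cbind(frags$start[fi], frags$end[fi])),
            source = "assembled", origin_bin = bin)
        } else {
          paths <- pe$paths_by_comp[[as.character(unit$id)]]
          tnum <- 0L
          for (p in paths) {
            ex <- cbind(start = frags$start[p], end = frags$end[p])
            # fuse fragments not separated by a junction boundary
            ex <- fuse_adjacent_exons(ex)
            ts1 <- transcript_set(
              transcript_id = "tmp", gene_id = gene_id, chrom = chrom,
              strand = ".", exons = list(ex), source = "assembled",
              origin_bin = bin)
            if (chain_key(ts1) %in% ref_chains) next
            # strand from the path's junction motifs
            jstr <- unique(e_strand[e_from %in% p & e_to %in% p])
            jstr <- setdiff(jstr, ".")
            ts1$strand <- if (length(jstr) == 1L) jstr else "."
            tnum <- tnum + 1L
            ts1$transcript_id <- sprintf("%s.t%d", gene_id, tnum)
            out[[length(out) + 1L]] <- ts1
          }
        }
      }
    }
  }
  if (!length(out)) return(empty_transcript_set())
  res <- do.call(bind_transcripts, out)
  if (!is.null(bin_span) && nrow(res)) {
    de_novo <- res$source == "assembled"
    contained <- tx_start(res) > bin_span[1] & tx_end(res) <= bin_span[2]
    res <- res[!de_novo | contained, , drop = FALSE]
  }
  res
}

fuse_adjacent_exons <- function(ex) {
  if (nrow(ex) < 2L) return(ex)
  keep_s <- ex[1L, 1L]; s <- c(); e <- c()
  cur_s <- ex[1L, 1L]; cur_e <- ex[1L, 2L]
  for (i in 2:nrow(ex)) {
    if (ex[i, 1L] <= cur_e + 1L) {
      cur_e <- max(cur_e, ex[i, 2L])
    } else {
      s <- c(s, cur_s); e <- c(e, cur_e)
      cur_s <- ex[i, 1L]; cur_e <- ex[i, 2L]
    }
  }
  s <- c(s, cur_s); e <- c(e, cur_e)
  cbind(start = s, end = e)
}

#' Assembler adapter contract (external tools)
#'
#' External genome-guided assemblers accept a coordinate-sorted
#' alignment file and emit GTF. These hooks construct the command a
#' user would run; they are not executed by the package's tests.
#'
#' @param name tool name.
#' @param command_template `sprintf` template with slots for the sorted
#'   alignment path and the output GTF path.
#' @return object of class `assembler_adapter`.
#' @export
assembler_adapter <- function(name, command_template) {
  structure(list(name = name, command_template = command_template),
            class = "assembler_adapter")
}

#' @rdname assembler_adapter
#' @export
stringtie_adapter <- function() {
  assembler_adapter("stringtie", "stringtie %s -o %s")
}

#' @rdname assembler_adapter
#' @export
scallop_adapter <- function() {
  assembler_adapter("scallop", "scallop -i %s -o %s")
}

#' Collect per-bin assemblies into one ordered transcript list
#'
#' Concatenates per-bin outputs in bin order (chromosome, then index),
#' preserving each bin's internal transcript order, so the result is
#' independent of bin completion order. Duplicates assembled by two
#' overlapping bins are both retained here; deduplication is the
#' downstream [remove_bin_redundancy()] step.
#'
#' @param per_bin named list of `transcript_set`s keyed by bin name.
#' @return a `transcript_set`.
#' @export
collect_transcripts <- function(per_bin) {
  if (!length(per_bin)) return(empty_transcript_set())
  check(!is.null(names(per_bin)), "per_bin must be a named list keyed by bin")
  ordered <- per_bin[order_bin_names(names(per_bin))]
  do.call(bind_transcripts, unname(ordered))
}
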