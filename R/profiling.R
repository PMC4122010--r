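#' Read alignments from tabular BLAST (outfmt 6) or SAM
#'
#' BLAST tabular columns follow outfmt 6 (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore). SAM input
#' (mapped segments only) is converted through Rsamtools/GenomicAlignments;
#' percent identity is derived from the NM tag over the reference-space
#' alignment length. Subject coordinates are normalized so start <= end
#' (1-based inclusive, the BLAST convention).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"blast6"` or `"sam"`.
#' @return data.frame with columns `query`, `subject`, `identity`,
#'   `length`, `start`, `end`, `bitscore`.
#' @export
read_alignments <- function(path, format = c("auto", "blast6", "sam")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "sam") "sam" else "blast6"
  }
  if (format == "sam") return(read_alignments_sam(path))

  tab <- tryCatch(
    utils::read.delim(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
  if (ncol(tab) < 12)
    stop("expected >= 12 BLAST outfmt-6 columns in ", path,
         ", found ", ncol(tab))
  bad <- which(!is.finite(suppressWarnings(as.numeric(tab[[3]]))) |
               !is.finite(suppressWarnings(as.numeric(tab[[4]]))))
  if (length(bad))
    stop("malformed alignment row(s) at line ", bad[1], " of ", path)
  out <- data.frame(query = as.character(tab[[1]]),
                    subject = as.character(tab[[2]]),
                    identity = as.numeric(tab[[3]]),
                    length = as.integer(tab[[4]]),
                    start = pmin(as.integer(tab[[9]]), as.integer(tab[[10]])),
                    end = pmax(as.integer(tab[[9]]), as.integer(tab[[10]])),
                    bitscore = as.numeric(tab[[12]]),
                    stringsAsFactors = FALSE)
  if (any(out$identity < 0 | out$identity > 100))
    stop("identity outside [0, 100] in ", path)
  if (any(out$length <= 0)) stop("non-positive alignment length in ", path)
  out
}

read_alignments_sam <- function(path) {
  for (pkg in c("Rsamtools", "GenomicAlignments")) {
    if (!requireNamespace(pkg, quietly = TRUE))
      stop("SAM input requires the ", pkg, " package")
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar"), tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))[[1]]
  if (length(res$qname) == 0)
    return(data.frame(query = character(0), subject = character(0),
                      identity = numeric(0), length = integer(0),
                      start = integer(0), end = integer(0),
                      bitscore = numeric(0), stringsAsFactors = FALSE))
  w <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar)
  nm <- res$tag$NM
  if (is.null(nm)) nm <- rep(0L, length(w))
  nm[is.na(nm)] <- 0L
  data.frame(query = res$qname,
             subject = as.character(res$rname),
             identity = 100 * (1 - nm / pmax(w, 1L)),
             length = w,
             start = res$pos,
             end = res$pos + w - 1L,
             bitscore = NA_real_,
             stringsAsFactors = FALSE)
}

#' Filter alignments by identity and mapping uniqueness
#'
#' Retains records with identity >= `min_identity`; with `unique_only`,
#' queries with more than one retained alignment are dropped entirely
#' (reads must map to a single position; bitscore ties are not rescued).
#'
#' @param records Alignment data.frame (see [read_alignments()]).
#' @param min_identity Minimum percent identity (default 99, the strain
#'   profiling cutoff).
#' @param unique_only Drop multi-mapping queries (default TRUE).
#' @return Filtered data.frame.
#' @export
filter_alignments <- function(records, min_identity = 99, unique_only = TRUE) {
  stopifnot(is.data.frame(records))
  keep <- records$identity >= min_identity
  out <- records[keep, , drop = FALSE]
  if (unique_only && nrow(out) > 1) {
    counts <- table(out$query)
    out <- out[out$query %in% names(counts)[counts == 1], , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Depth and breadth of genome coverage
#'
#' Depth is the mean fold coverage, sum of aligned subject spans divided
#' by the genome length; breadth is the fraction of genome positions
#' covered at least once (interval union).
#'
#' @param records Alignment data.frame with `start`, `end` (1-based
#'   inclusive).
#' @param genome_length Genome length in bp.
#' @return Named list with `depth` and `breadth`.
#' @export
genome_coverage <- function(records, genome_length) {
  stopifnot(genome_length >= 1)
  if (nrow(records) == 0) return(list(depth = 0, breadth = 0))
  if (any(records$start < 1 | records$end > genome_length))
    stop("alignment coordinates outside [1, ", genome_length, "]")
  spans <- records$end - records$start + 1
  depth <- sum(spans) / genome_length
  ir <- IRanges::reduce(IRanges::IRanges(records$start, records$end))
  breadth <- sum(IRanges::width(ir)) / genome_length
  list(depth = depth, breadth = breadth)
}

#' Per-sample, per-strain coverage table from alignment lists
#'
#' Applies the identity/uniqueness filter to each sample's alignments,
#' computes depth and breadth per subject (strain reference), and
#' completes missing sample-strain pairs with zero coverage so that
#' cohort prevalences are computed over all samples.
#'
#' @param alignments List (one element per sample) of alignment
#'   data.frames (see [read_alignments()]).
#' @param genome_length Reference genome length in bp (scalar, or named
#'   vector by strain).
#' @param strains Strain universe; defaults to all subjects observed
#'   after filtering.
#' @param min_identity,unique_only Passed to [filter_alignments()].
#' @return data.frame with columns `sample`, `strain`, `depth`, `breadth`.
#' @export
coverage_table <- function(alignments, genome_length, strains = NULL,
                           min_identity = 99, unique_only = TRUE) {
  stopifnot(is.list(alignments))
  filtered <- lapply(alignments, filter_alignments,
                     min_identity = min_identity, unique_only = unique_only)
  if (is.null(strains))
    strains <- sort(unique(unlist(lapply(filtered, function(d) d$subject))))
  glen <- if (length(genome_length) == 1)
    stats::setNames(rep(genome_length, length(strains)), strains)
  else genome_length
  out <- expand.grid(sample = seq_along(alignments), strain = strains,
                     stringsAsFactors = FALSE)
  out$depth <- 0; out$breadth <- 0
  for (i in seq_along(filtered)) {
    d <- filtered[[i]]
    for (s in intersect(unique(d$subject), strains)) {
      gc <- genome_coverage(d[d$subject == s, , drop = FALSE], glen[[s]])
      k <- out$sample == i & out$strain == s
      out$depth[k] <- gc$depth
      out$breadth[k] <- gc$breadth
    }
  }
  out[order(out$sample, out$strain), , drop = FALSE]
}

#' Call strain presence from coverage summaries
#'
#' A strain is called present when its mean depth of coverage reaches
#' `depth_threshold` (boundary inclusive; default 10-fold). When a
#' `sample` column is present, per-strain prevalence across samples is
#' computed and strains are ordered by descending prevalence.
#'
#' @param coverages data.frame with columns `strain`, `depth`, `breadth`
#'   and optionally `sample`.
#' @param depth_threshold Presence threshold on depth (> 0, default 10).
#' @return A `strain_call` data.frame: input plus `present`; attribute
#'   `prevalence` (data.frame strain, prevalence) when samples given.
#' @export
call_strains <- function(coverages, depth_threshold = 10) {
  stopifnot(depth_threshold > 0, is.data.frame(coverages),
            all(c("strain", "depth") %in% names(coverages)))
  out <- coverages
  out$present <- out$depth >= depth_threshold
  attr(out, "depth_threshold") <- depth_threshold
  if ("sample" %in% names(out)) {
    prev <- stats::aggregate(present ~ strain, data = out, FUN = mean)
    names(prev)[2] <- "prevalence"
    prev <- prev[order(-prev$prevalence, prev$strain), , drop = FALSE]
    rownames(prev) <- NULL
    out <- out[order(match(out$strain, prev$strain), out$sample), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "prevalence") <- prev
  }
  class(out) <- c("strain_call", "data.frame")
  out
}

#' Gene coverage by single scaffolds
#'
#' For each gene interval, the covered fraction is the maximum over
#' individual scaffold alignments of (overlap length / gene length) —
#' the single-scaffold rule: coverage from multiple scaffolds is not
#' summed. A gene counts as covered when the fraction reaches
#' `min_fraction` (boundary inclusive; default 0.8). Any identity
#' filtering is applied upstream via [filter_alignments()].
#'
#' @param records Scaffold alignment data.frame (`start`, `end`).
#' @param genes data.frame with columns `gene`, `start`, `end` (1-based
#'   inclusive intervals on the subject genome).
#' @param min_fraction Covered-fraction threshold (default 0.8).
#' @return data.frame with columns `gene`, `length`, `fraction`, `covered`.
#' @export
gene_coverage_from_scaffolds <- function(records, genes, min_fraction = 0.8) {
  stopifnot(is.data.frame(genes),
            all(c("gene", "start", "end") %in% names(genes)))
  glen <- genes$end - genes$start + 1
  if (any(glen <= 0))
    stop("zero- or negative-length gene(s): ",
         paste(genes$gene[glen <= 0], collapse = ", "))
  out <- data.frame(gene = genes$gene, length = glen,
                    fraction = 0, covered = FALSE, stringsAsFactors = FALSE)
  if (nrow(records) > 0) {
    gi <- IRanges::IRanges(genes$start, genes$end)
    ai <- IRanges::IRanges(records$start, records$end)
    hits <- IRanges::findOverlaps(gi, ai)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      ov <- IRanges::width(IRanges::pintersect(gi[qh], ai[sh]))
      frac <- ov / glen[qh]
      best <- tapply(frac, qh, max)
      out$fraction[as.integer(names(best))] <- as.numeric(best)
    }
  }
  out$covered <- out$fraction >= min_fraction
  out
}

#' One-sided enrichment test (Fisher exact / hypergeometric tail)
#'
#' Tests whether a gene set is enriched for covered genes: given
#' `covered_in_set` covered genes among `set_size` in the set, with
#' `covered_total` covered genes in a universe of size `universe`,
#' computes the upper hypergeometric tail P(X >= covered_in_set) — the
#' one-sided Fisher exact test in the enrichment direction — in log
#' space, so p-values far below double precision are still reported via
#' their log.
#'
#' @param covered_in_set,set_size,covered_total,universe Contingency
#'   counts; must satisfy covered_in_set <= set_size <= universe,
#'   covered_in_set <= covered_total <= universe.
#' @return List with `p_value`, `log10_p` and the 2x2 `table`.
#' @export
enrichment_test <- function(covered_in_set, set_size, covered_total, universe) {
  k <- covered_in_set; n <- set_size; K <- covered_total; N <- universe
  if (!(k >= 0 && k <= n && n <= N && k <= K && K <= N &&
        (n - k) <= (N - K)))
    stop("inconsistent contingency margins")
  logp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2, 2,
                dimnames = list(c("in_set", "not_in_set"),
                                c("covered", "not_covered")))
  list(p_value = exp(logp), log10_p = logp / log(10), table = t(tab))
}
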