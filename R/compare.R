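# Cross-cohort comparative epigenomics: per-cohort top-DMP signatures,
# directional percent-shared overlap, tree-and-leaf aggregation,
# CpG-island shore/shelf annotation and category enrichment, plus the
# loss-of-function transcript-fraction reporting utility.

#' Build a cohort DMP signature
#'
#' Filters a DMP table to `q < 0.05` (strict), sorts by p ascending (ties
#' by `|delta_beta|` descending, then probe id) and truncates at 500
#' probes; cohorts with fewer significant probes keep all of them. When no
#' probe passes, an empty signature is returned with a warning rather
#' than an error.
#'
#' @param dmp A [dmp_table()] data.frame.
#' @param name Cohort name.
#' @param q_max FDR cutoff (default 0.05, strict `<`).
#' @param max_probes Signature size cap (default 500).
#' @return Object of class `cohort_signature`: list with `name`, `probes`
#'   (data.frame `probe_id`, `delta_beta`, `p`, `q`) and `rule`.
#' @export
build_cohort_signature <- function(dmp, name, q_max = 0.05, max_probes = 500L) {
  pass <- dmp$q < q_max
  sig <- dmp[pass, , drop = FALSE]
  if (nrow(sig) == 0L)
    warning(sprintf("cohort '%s': no probes at FDR < %g; empty signature",
                    name, q_max))
  ord <- order(sig$p, -abs(sig$delta_beta), sig$probe_id)
  sig <- sig[ord, , drop = FALSE]
  sig <- sig[seq_len(min(max_probes, nrow(sig))), , drop = FALSE]
  rownames(sig) <- NULL
  structure(list(name = name,
                 probes = sig[, c("probe_id", "delta_beta", "p", "q")],
                 rule = sprintf("q < %g, top %d by ascending p", q_max, max_probes)),
            class = "cohort_signature")
}

#' Directional percent-shared overlap between cohort signatures
#'
#' Entry `(y, x)` is `100 * |DMP_y intersect DMP_x| / |DMP_y|`: the
#' percentage of the row cohort's probes also present in the column
#' cohort's signature. The matrix is generally asymmetric; the diagonal
#' is 100.
#'
#' @param signatures List of `cohort_signature` objects with unique names.
#' @return Numeric percent matrix with cohort dimnames.
#' @export
overlap_matrix <- function(signatures) {
  if (length(signatures) < 2L)
    stop_episign("argument_error", "need at least 2 signatures")
  nms <- vapply(signatures, `[[`, character(1L), "name")
  if (anyDuplicated(nms))
    stop_episign("argument_error", "duplicate cohort names: %s",
                 paste(unique(nms[duplicated(nms)]), collapse = ", "))
  sets <- lapply(signatures, function(s) s$probes$probe_id)
  k <- length(sets)
  out <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  for (y in seq_len(k)) for (x in seq_len(k))
    out[y, x] <- 100 * length(intersect(sets[[y]], sets[[x]])) / length(sets[[y]])
  out
}

#' Tree-and-leaf aggregation of cohort signatures
#'
#' Places each cohort in the union feature space of all signatures, with
#' its per-probe mean methylation difference (delta-beta) as the value and
#' 0 where a probe is absent from its signature, then clusters cohorts
#' with Euclidean distance and Ward linkage. Leaf attributes carry the
#' signature size (node size in a tree-and-leaf plot) and the mean
#' methylation difference (node color).
#'
#' @param signatures List of `cohort_signature` objects (>= 2).
#' @return List of class `cohort_tree` with `hclust`, `leaf_stats`
#'   (data.frame `cohort`, `n_dmps`, `mean_delta`) and the feature
#'   `matrix` used.
#' @export
cohort_tree <- function(signatures) {
  if (length(signatures) < 2L)
    stop_episign("argument_error", "need at least 2 signatures")
  nms <- vapply(signatures, `[[`, character(1L), "name")
  union_probes <- sort(unique(unlist(lapply(signatures,
                                            function(s) s$probes$probe_id))))
  if (length(union_probes) == 0L)
    stop_episign("argument_error", "all signatures are empty")
  mat <- matrix(0, nrow = length(signatures), ncol = length(union_probes),
                dimnames = list(nms, union_probes))
  for (i in seq_along(signatures)) {
    pr <- signatures[[i]]$probes
    mat[i, pr$probe_id] <- pr$delta_beta
  }
  ord <- order(nms)
  hc <- stats::hclust(stats::dist(mat[ord, , drop = FALSE],
                                  method = "euclidean"),
                      method = "ward.D2")
  leaf_stats <- data.frame(
    cohort = nms,
    n_dmps = vapply(signatures, function(s) nrow(s$probes), integer(1L)),
    mean_delta = vapply(signatures, function(s)
      if (nrow(s$probes)) mean(s$probes$delta_beta) else NA_real_, numeric(1L)),
    stringsAsFactors = FALSE)
  structure(list(hclust = hc, leaf_stats = leaf_stats, matrix = mat),
            class = "cohort_tree")
}

#' Annotate probes with gene-region and CpG-island context
#'
#' Assigns each probe exactly one CpG-island relation: `island` if its
#' position falls inside a CpG island, `shore` if the distance to the
#' nearest island boundary is in (0, 2000] bp, `shelf` for (2000, 4000]
#' bp, and `open_sea` beyond. The gene-region category is carried through
#' from the annotation table. Probe positions are 1-based; CGI intervals
#' are read from BED (0-based half-open) and converted on import.
#'
#' @param probe_ids Character vector of probes to annotate.
#' @param annotation Data.frame with columns `probe_id`, `chrom`, `pos`
#'   (1-based) and `gene_region`.
#' @param cgi Path to a CpG-island BED file, or a `GRanges` of island
#'   intervals.
#' @return Data.frame with `probe_id`, `gene_region`, `cgi_relation`.
#' @export
annotate_probes <- function(probe_ids, annotation, cgi) {
  idx <- match(probe_ids, annotation$probe_id)
  if (anyNA(idx))
    stop_episign("annotation_error", "probe(s) missing from annotation: %s",
                 paste(utils::head(probe_ids[is.na(idx)], 10L), collapse = ", "))
  ann <- annotation[idx, , drop = FALSE]
  islands <- if (methods::is(cgi, "GRanges")) cgi else rtracklayer::import(cgi, format = "BED")
  probes <- GenomicRanges::GRanges(ann$chrom,
                                   IRanges::IRanges(ann$pos, ann$pos))
  # chromosomes without any island are legitimate (open sea), so the
  # disjoint-seqlevels warning is expected
  inside <- suppressWarnings(
    GenomicRanges::countOverlaps(probes, islands) > 0L)
  # distance() counts the gap between disjoint ranges, so the distance to
  # the island boundary itself is gap + 1
  near <- suppressWarnings(
    GenomicRanges::distanceToNearest(probes, islands))
  boundary_dist <- rep(Inf, length(probes))
  boundary_dist[S4Vectors::queryHits(near)] <-
    S4Vectors::mcols(near)$distance + 1
  relation <- ifelse(inside, "island",
                     ifelse(boundary_dist <= 2000, "shore",
                            ifelse(boundary_dist <= 4000, "shelf", "open_sea")))
  data.frame(probe_id = ann$probe_id,
             gene_region = ann$gene_region,
             cgi_relation = relation,
             stringsAsFactors = FALSE)
}

#' Category enrichment of a signature against background probes
#'
#' For every category on both annotation axes (gene region and CGI
#' relation), builds the 2x2 table of signature/background membership
#' against category membership, computes the Fisher exact p-value and the
#' odds ratio (with a Haldane 0.5 correction when a cell is zero), and
#' adjusts p-values across categories by Benjamini-Hochberg.
#'
#' @param signature_contexts [annotate_probes()] output for the signature
#'   probes.
#' @param background_contexts Annotation for the background probe set
#'   (strictly larger than the signature; signature probes are excluded
#'   from the background counts if present).
#' @return Data.frame with `axis`, `category`, counts, proportions,
#'   `odds_ratio`, `or_flag` (`finite`/`infinite`/`undefined`), `p`, `q`.
#' @export
context_enrichment <- function(signature_contexts, background_contexts) {
  bg <- background_contexts[!background_contexts$probe_id %in%
                              signature_contexts$probe_id, , drop = FALSE]
  if (nrow(bg) <= nrow(signature_contexts))
    stop_episign("argument_error",
                 "background must be strictly larger than the signature")
  rows <- list()
  for (axis in c("gene_region", "cgi_relation")) {
    cats <- sort(unique(c(signature_contexts[[axis]], bg[[axis]])))
    for (cat in cats) {
      a <- sum(signature_contexts[[axis]] == cat)
      b <- nrow(signature_contexts) - a
      c_ <- sum(bg[[axis]] == cat)
      d <- nrow(bg) - c_
      if (c_ == 0L && a > 0L) {
        or <- NA_real_; flag <- "undefined"; p <- stats::fisher.test(
          matrix(c(a, b, c_, d), 2L, byrow = TRUE))$p.value
      } else {
        p <- stats::fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE))$p.value
        if (any(c(a, b, c_, d) == 0L)) {
          or <- (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c_ + 0.5))
          flag <- if (b == 0L || c_ == 0L) "infinite" else "finite"
        } else {
          or <- a * d / (b * c_)
          flag <- "finite"
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        axis = axis, category = cat,
        n_signature = a, n_background = c_,
        proportion_signature = a / nrow(signature_contexts),
        proportion_background = c_ / nrow(bg),
        odds_ratio = or, or_flag = flag, p = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}

#' Loss-of-function transcript fraction
#'
#' Summarizes mRNA splicing quantification for a splice-affecting variant:
#' the percentage of transcripts with a loss-of-function effect is the sum
#' of the aberrantly spliced classes (exon skipping and intron retention);
#' normally spliced transcripts and the fraction lost to nonsense-mediated
#' decay are excluded. Fractions must sum to 100 within 0.5.
#'
#' @param exon_skipping,intron_retention,normal,nmd Percentages in
#'   `[0, 100]`.
#' @return The loss-of-function percentage.
#' @export
lof_transcript_fraction <- function(exon_skipping, intron_retention, normal,
                                    nmd) {
  vals <- c(exon_skipping = exon_skipping, intron_retention = intron_retention,
            normal = normal, nmd = nmd)
  if (any(vals < 0 | vals > 100))
    stop_episign("argument_error", "fractions must lie in [0, 100]")
  if (abs(sum(vals) - 100) > 0.5)
    stop_episign("consistency_error",
                 "transcript fractions sum to %.2f; expected 100 +/- 0.5",
                 sum(vals))
  exon_skipping + intron_retention
}

#' Write comparative outputs
#'
#' @param sig A `cohort_signature`.
#' @param path Output path.
#' @export
write_cohort_signature <- function(sig, path) {
  data.table::fwrite(sig$probes, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_signature
#' @param mat An [overlap_matrix()] result.
#' @export
write_overlap_matrix <- function(mat, path) {
  dt <- data.table::data.table(cohort = rownames(mat))
  for (j in seq_len(ncol(mat)))
    data.table::set(dt, j = colnames(mat)[j], value = mat[, j])
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_signature
#' @param tree A [cohort_tree()] result; writes Newick plus a node
#'   attribute TSV alongside.
#' @export
write_cohort_tree <- function(tree, path) {
  write_newick(tree$hclust, path)
  data.table::fwrite(tree$leaf_stats, paste0(path, ".leaves.tsv"),
                     sep = "\t", quote = FALSE)
  invisible(path)
}
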