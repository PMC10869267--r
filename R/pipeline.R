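#' Run the allelic 4C-seq analysis end to end
#'
#' Composes the 4C stages: demultiplex pairs by viewpoint allele, tag the
#' interacting mates, apply the MAPQ filter, count exact fragend hits,
#' drop the bait-flanking fragends, build smoothed rpm and log2 ratio
#' tracks, call near-bait domains per allele, and run the paired
#' maternal-vs-paternal differential test.
#'
#' @param pairs viewpoint-mate pair table (see
#'   [demultiplex_viewpoint_pairs()]).
#' @param interacting interacting-mate alignment table in reference
#'   coordinates (`qname`, `chrom`, `start`, `end`, `strand`, `mapq`,
#'   `replicate`).
#' @param vp a [viewpoint_spec()].
#' @param fragmap a `FragmentMap` of the reference.
#' @param chrom,bait_pos bait location (0-based).
#' @param k fragends per smoothing/calling window (default 8).
#' @param region near-bait half-width in bp (default 1e6).
#' @param alpha significance threshold on BH-adjusted p (default 0.05).
#' @return list with `demux` (tagged pairs), `fragends` (`FragendTable`),
#'   `tracks` (smoothed rpm), `ratio` (log2 maternal/paternal on the
#'   fragend grid), `domains` (per-allele domain calls), `differential`
#'   (an `InteractionCallSet`).
#' @export
fourc_run <- function(pairs, interacting, vp, fragmap, chrom, bait_pos,
                      k = 8L, region = 1e6, alpha = 0.05) {
  demux <- demultiplex_viewpoint_pairs(pairs, vp)
  tag <- stats::setNames(demux$allele, demux$qname)
  aln <- interacting[interacting$qname %in% demux$qname, , drop = FALSE]
  aln$allele <- unname(tag[aln$qname])
  aln <- aln[aln$mapq >= vp$mapq_min, , drop = FALSE]
  tab <- count_fragends(aln, fragmap)
  tab <- exclude_bait_fragends(tab, fragmap, chrom, bait_pos)
  tracks <- fragend_rpm_smooth(tab, fragmap, chrom, k = k)
  ratio <- interaction_ratio_track(tracks$mean[["maternal"]],
                                   tracks$mean[["paternal"]])
  domains <- lapply(stats::setNames(nm = c("maternal", "paternal")),
                    function(al)
    call_interaction_domains(tab, fragmap, chrom, bait_pos, allele = al,
                             k = k, region = region, alpha = alpha))
  diff <- differential_allelic_interactions(tab, fragmap, chrom, bait_pos,
                                            k = k, region = region,
                                            alpha = alpha)
  list(demux = demux, fragends = tab, tracks = tracks, ratio = ratio,
       domains = domains, differential = diff)
}

#' Build all alignment targets for a hybrid design
#'
#' One call producing what hybrid pipelines align against: the N-masked
#' reference, the variant-strain pseudogenome with its lift map, and the
#' diploid genome.
#'
#' @param ref reference `DNAStringSet`.
#' @param variants a `VariantSet` for strain B.
#' @param strain_a,strain_b strain names (A = reference strain).
#' @return list with `masked`, `pseudo`, `liftmap`, `liftmaps` (per-strain
#'   named list; A is `NULL` identity), `diploid`.
#' @export
build_hybrid_genomes <- function(ref, variants, strain_a = "B6",
                                 strain_b = "JF1") {
  masked <- mask_reference(ref, variants)
  pg <- build_pseudogenome(ref, variants)
  diploid <- build_diploid_genome(ref, pg$seq, strain_a, strain_b)
  list(masked = masked, pseudo = pg$seq, liftmap = pg$liftmap,
       liftmaps = stats::setNames(list(NULL, pg$liftmap),
                                  c(strain_a, strain_b)),
       diploid = diploid)
}
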