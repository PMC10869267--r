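#' In silico restriction digestion of a genome
#'
#' Cuts every chromosome immediately before each occurrence of the enzyme
#' recognition site (default `GATC`, DpnII/MboI). Fragments tile each
#' chromosome exactly; the fragend grid is the sorted unique set of
#' fragment boundaries (cut positions plus the two contig ends), since an
#' internal cut is both the right end of one fragment and the left end of
#' the next. Valid 4C ligation products map exactly at fragends.
#'
#' @param genome a `DNAStringSet`.
#' @param site recognition site, uppercase ACGT (default `"GATC"`).
#' @return a `FragmentMap`: list with `fragments` (per-chrom data.frame of
#'   0-based half-open intervals), `fragends` (per-chrom integer vector of
#'   boundary positions), `site`, `seqlengths`.
#' @export
digest_genome <- function(genome, site = "GATC") {
  if (!grepl("^[ACGT]+$", site)) stop("site must be non-empty uppercase ACGT")
  fragments <- list(); fragends <- list()
  for (chrom in names(genome)) {
    len <- length(genome[[chrom]])
    hits <- Biostrings::start(Biostrings::matchPattern(site, genome[[chrom]]))
    cuts <- hits - 1L                       # 0-based cut-before positions
    cuts <- cuts[cuts > 0L & cuts < len]    # a cut at 0 adds no boundary
    bounds <- c(0L, cuts, len)
    fragments[[chrom]] <- data.frame(start = utils::head(bounds, -1L),
                                     end = bounds[-1L])
    fragends[[chrom]] <- bounds
  }
  structure(list(fragments = fragments, fragends = fragends,
                 site = site,
                 seqlengths = stats::setNames(
                   vapply(genome, length, 0L), names(genome))),
            class = "FragmentMap")
}

#' @export
print.FragmentMap <- function(x, ...) {
  nf <- vapply(x$fragments, nrow, 0L)
  cat("FragmentMap (site ", x$site, "): ", sum(nf), " fragments over ",
      length(nf), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Viewpoint specification for allelic 4C-seq
#'
#' Describes the bait: its reference interval, the strain-discriminating
#' SNP inside it (with the base carried by each parental allele under the
#' cross of interest), read trimming for the interacting mate, and the
#' MAPQ threshold for the viewpoint-mate alignment.
#'
#' @param chrom viewpoint chromosome.
#' @param start,end 0-based half-open viewpoint interval.
#' @param snp_pos 1-based reference position of the viewpoint SNP (must lie
#'   inside the interval).
#' @param snp_maternal,snp_paternal single bases carried by the maternal /
#'   paternal allele at `snp_pos`; must differ.
#' @param trim5,trim3 bases trimmed from the interacting mate's 5'/3' ends
#'   (defaults 10 / 0; trim3 is viewpoint-specific).
#' @param mapq_min minimum viewpoint-mate MAPQ (default 10).
#' @return a `ViewpointSpec` object.
#' @export
viewpoint_spec <- function(chrom, start, end, snp_pos, snp_maternal,
                           snp_paternal, trim5 = 10L, trim3 = 0L,
                           mapq_min = 10L) {
  if (snp_pos - 1L < start || snp_pos - 1L >= end)
    stop("viewpoint SNP must lie inside the viewpoint interval")
  if (toupper(snp_maternal) == toupper(snp_paternal))
    stop("uninformative viewpoint: maternal and paternal SNP bases identical")
  structure(list(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), snp_pos = as.integer(snp_pos),
                 snp_maternal = toupper(snp_maternal),
                 snp_paternal = toupper(snp_paternal),
                 trim5 = as.integer(trim5), trim3 = as.integer(trim3),
                 mapq_min = as.integer(mapq_min)),
            class = "ViewpointSpec")
}

#' Read / write a viewpoint spec as a key=value config file
#'
#' Plain-text format, one `key = value` per line (`chrom`, `start`, `end`,
#' `snp_pos`, `snp_maternal`, `snp_paternal`, `trim5`, `trim3`,
#' `mapq_min`); `#` starts a comment.
#'
#' @param path file path.
#' @return a `ViewpointSpec`.
#' @export
read_viewpoint_spec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  num <- function(k, d = NULL) if (k %in% names(vals))
    as.integer(vals[[k]]) else d
  viewpoint_spec(chrom = vals[["chrom"]], start = num("start"),
                 end = num("end"), snp_pos = num("snp_pos"),
                 snp_maternal = vals[["snp_maternal"]],
                 snp_paternal = vals[["snp_paternal"]],
                 trim5 = num("trim5", 10L), trim3 = num("trim3", 0L),
                 mapq_min = num("mapq_min", 10L))
}

#' @rdname read_viewpoint_spec
#' @param vp a `ViewpointSpec`.
#' @export
write_viewpoint_spec <- function(vp, path) {
  writeLines(paste(names(unclass(vp)),
                   vapply(unclass(vp), as.character, ""), sep = " = "), path)
  invisible(path)
}

#' Demultiplex 4C read pairs by viewpoint allele
#'
#' The viewpoint-proximal mate of each pair is expected to align to the
#' viewpoint interval; the base it carries at the viewpoint SNP assigns the
#' pair to the maternal or paternal bait allele. Pairs are discarded (and
#' counted in the report) when the viewpoint alignment misses the viewpoint
#' coordinates, falls below `vp$mapq_min`, does not cover the SNP, or
#' carries a base matching neither parental allele (including `N`). The
#' interacting mate's sequence, when present, is returned trimmed by
#' `trim5`/`trim3`.
#'
#' @param pairs data.frame with one row per read pair: `qname`,
#'   `vp_chrom`, `vp_start` (0-based), `vp_end`, `vp_mapq`, `vp_seq`
#'   (viewpoint-mate alignment), optionally `int_seq` (raw interacting-mate
#'   sequence) and `replicate`.
#' @param vp a [viewpoint_spec()].
#' @return data.frame of retained pairs with an `allele` column
#'   (`"maternal"`/`"paternal"`) and, when `int_seq` was present,
#'   `int_seq_trimmed`; drop counts are in the `"report"` attribute.
#' @export
demultiplex_viewpoint_pairs <- function(pairs, vp) {
  if (vp$snp_maternal == vp$snp_paternal)
    stop("uninformative viewpoint: identical parental SNP bases")
  n <- nrow(pairs)
  on_vp <- pairs$vp_chrom == vp$chrom &
    pairs$vp_start < vp$end & pairs$vp_end > vp$start
  hi_q <- pairs$vp_mapq >= vp$mapq_min
  off <- (vp$snp_pos - 1L) - pairs$vp_start
  covers <- off >= 0L & off < nchar(pairs$vp_seq)
  base <- rep(NA_character_, n)
  ok0 <- on_vp & hi_q & covers
  base[ok0] <- toupper(substr(pairs$vp_seq[ok0], off[ok0] + 1L, off[ok0] + 1L))
  allele <- ifelse(base == vp$snp_maternal, "maternal",
                   ifelse(base == vp$snp_paternal, "paternal", NA))
  keep <- !is.na(allele)
  out <- pairs[keep, , drop = FALSE]
  out$allele <- allele[keep]
  if (!is.null(out$int_seq)) {
    len <- nchar(out$int_seq)
    out$int_seq_trimmed <- substr(out$int_seq, vp$trim5 + 1L,
                                  pmax(len - vp$trim3, vp$trim5))
  }
  rownames(out) <- NULL
  attr(out, "report") <- list(
    n_pairs = n, n_kept = sum(keep),
    n_off_viewpoint = sum(!on_vp),
    n_low_mapq = sum(on_vp & !hi_q),
    n_snp_uncovered = sum(on_vp & hi_q & !covers),
    n_allele_mismatch = sum(ok0 & is.na(allele)))
  out
}

#' Fragends flanking the bait fragment
#'
#' The two boundaries of the restriction fragment containing the bait;
#' these carry self-ligation and undigested products and are excluded from
#' normalization and testing by default.
#'
#' @param fragmap a `FragmentMap`.
#' @param chrom chromosome.
#' @param bait_pos 0-based bait position.
#' @return integer vector of two fragend positions.
#' @export
bait_fragends <- function(fragmap, chrom, bait_pos) {
  fr <- fragmap$fragments[[chrom]]
  i <- which(fr$start <= bait_pos & fr$end > bait_pos)
  if (length(i) != 1L) stop("bait position outside ", chrom)
  c(fr$start[i], fr$end[i])
}

#' Count alignments mapped exactly to fragment ends
#'
#' The defining 4C filter: a plus-strand alignment is counted for fragend
#' `b` iff its start equals a fragment's left boundary `b`; a minus-strand
#' alignment iff its end equals a fragment's right boundary. Alignments
#' matching no fragend are dropped and reported. Counts are keyed by
#' `(chrom, fragend, allele, replicate)`.
#'
#' @param aln alignment table in reference coordinates with `allele` and
#'   (optionally) `replicate` columns; `start`/`end` 0-based half-open.
#' @param fragmap a `FragmentMap`.
#' @return a `FragendTable` data.frame (`chrom`, `fragend`, `allele`,
#'   `replicate`, `count`) with per-(allele, replicate) totals and the
#'   dropped-read count in attributes.
#' @export
count_fragends <- function(aln, fragmap) {
  chrom <- aln$chrom %||% aln$rname
  if (is.null(aln$replicate)) aln$replicate <- 1L
  fe <- rep(NA_integer_, nrow(aln))
  for (chr in unique(chrom)) {
    fr <- fragmap$fragments[[chr]]
    if (is.null(fr)) next
    rows <- which(chrom == chr)
    plus <- aln$strand[rows] != "-"
    fe[rows[plus]] <- ifelse(aln$start[rows[plus]] %in% fr$start,
                             aln$start[rows[plus]], NA_integer_)
    fe[rows[!plus]] <- ifelse(aln$end[rows[!plus]] %in% fr$end,
                              aln$end[rows[!plus]], NA_integer_)
  }
  keep <- !is.na(fe)
  tab <- stats::aggregate(
    list(count = rep(1L, sum(keep))),
    by = list(chrom = chrom[keep], fragend = fe[keep],
              allele = aln$allele[keep], replicate = aln$replicate[keep]),
    FUN = sum)
  tab <- tab[order(tab$chrom, tab$allele, tab$replicate, tab$fragend), ,
             drop = FALSE]
  rownames(tab) <- NULL
  totals <- stats::aggregate(list(total = tab$count),
                             by = list(allele = tab$allele,
                                       replicate = tab$replicate),
                             FUN = sum)
  attr(tab, "totals") <- totals
  attr(tab, "n_dropped") <- sum(!keep)
  class(tab) <- c("FragendTable", "data.frame")
  tab
}

#' Drop the bait-flanking fragends from a FragendTable
#'
#' @param tab a `FragendTable`.
#' @param fragmap a `FragmentMap`.
#' @param chrom,bait_pos bait location (0-based).
#' @return the filtered `FragendTable` with recomputed totals.
#' @export
exclude_bait_fragends <- function(tab, fragmap, chrom, bait_pos) {
  bf <- bait_fragends(fragmap, chrom, bait_pos)
  keep <- !(tab$chrom == chrom & tab$fragend %in% bf)
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) > 0L) {
    totals <- stats::aggregate(list(total = out$count),
                               by = list(allele = out$allele,
                                         replicate = out$replicate),
                               FUN = sum)
  } else totals <- data.frame(allele = character(), replicate = integer(),
                              total = integer())
  attr(out, "totals") <- totals
  attr(out, "n_dropped") <- attr(tab, "n_dropped")
  class(out) <- class(tab)
  out
}

# Dense per-fragend count vector on the full grid for one chromosome.
fragend_vector <- function(tab, fragmap, chrom, allele, replicate = NULL) {
  grid <- fragmap$fragends[[chrom]]
  sel <- tab$chrom == chrom & tab$allele == allele
  if (!is.null(replicate)) sel <- sel & tab$replicate == replicate
  v <- stats::setNames(numeric(length(grid)), grid)
  if (any(sel)) {
    agg <- tapply(tab$count[sel], tab$fragend[sel], sum)
    v[as.character(names(agg))] <- as.numeric(agg)
  }
  unname(v)
}

#' Smoothed rpm tracks per allele
#'
#' Converts fragend counts to reads-per-million of informative (counted)
#' reads, per allele and replicate, then smooths with a centered running
#' mean over `k` consecutive fragends (edge windows shrink). Per-replicate
#' and replicate-averaged tracks are returned on the full fragend grid.
#'
#' @param tab a `FragendTable` (bait fragends already excluded if desired).
#' @param fragmap a `FragmentMap`.
#' @param chrom chromosome to build tracks for.
#' @param k smoothing window in fragends (default 8, shared with the
#'   domain caller).
#' @param combined_denominator use the summed (maternal + paternal) total
#'   per replicate as the rpm denominator instead of the per-allele total.
#' @return list with `grid` (fragend positions), `rpm` and `smoothed`
#'   (named list `allele -> matrix fragends x replicates`), and `mean`
#'   (named list `allele -> replicate-averaged smoothed vector`).
#' @export
fragend_rpm_smooth <- function(tab, fragmap, chrom, k = 8L,
                               combined_denominator = FALSE) {
  grid <- fragmap$fragends[[chrom]]
  totals <- attr(tab, "totals")
  alleles <- sort(unique(tab$allele))
  reps <- sort(unique(tab$replicate))
  rpm <- smoothed <- list()
  for (al in alleles) {
    m <- matrix(NA_real_, length(grid), length(reps),
                dimnames = list(NULL, reps))
    sm <- m
    for (j in seq_along(reps)) {
      cnt <- fragend_vector(tab, fragmap, chrom, al, reps[j])
      tot <- if (combined_denominator)
        sum(totals$total[totals$replicate == reps[j]])
      else sum(totals$total[totals$allele == al & totals$replicate == reps[j]])
      if (length(tot) == 0L || tot == 0L) {
        warning("allele ", al, " absent in replicate ", reps[j],
                "; rpm track set to NA")
        next
      }
      m[, j] <- cnt * 1e6 / tot
      sm[, j] <- running_mean(m[, j], k)
    }
    rpm[[al]] <- m
    smoothed[[al]] <- sm
  }
  mean_tracks <- lapply(smoothed, function(sm) rowMeans(sm, na.rm = TRUE))
  list(grid = grid, rpm = rpm, smoothed = smoothed, mean = mean_tracks)
}

#' Maternal/paternal log2 interaction-ratio track
#'
#' `log2((mat + c) / (pat + c))` with pseudocount `c` (default 1
#' rpm-equivalent), so the ratio is 0 where both tracks are empty and
#' swapping the tracks negates the output exactly.
#'
#' @param maternal,paternal numeric tracks on the same fragend grid.
#' @param pseudocount pseudocount `c`.
#' @return numeric vector of log2 ratios.
#' @export
interaction_ratio_track <- function(maternal, paternal, pseudocount = 1) {
  if (length(maternal) != length(paternal))
    stop("maternal and paternal tracks are on different grids")
  log2((maternal + pseudocount) / (paternal + pseudocount))
}

#' Tile the near-bait fragend grid into windows of k fragends
#'
#' Takes the fragends within `region` of the bait (excluding, by default,
#' the two bait-fragment fragends), in genomic order, and groups them into
#' consecutive non-overlapping windows of `k`; a trailing partial window is
#' dropped.
#'
#' @param fragmap a `FragmentMap`.
#' @param chrom chromosome.
#' @param bait_pos 0-based bait position.
#' @param k fragends per window (default 8).
#' @param region near-bait half-width in bp (default 1e6).
#' @param exclude_bait drop the bait-fragment fragends first (default TRUE).
#' @return data.frame with one row per window: `window`, `start`, `end`
#'   (0-based, outermost fragends), `n_fragends`, `dist` (harmonic-mean
#'   fragend distance to bait: under inverse-power contact decay a
#'   window's mass is dominated by its nearest fragends, and the harmonic
#'   mean is the aggregation that keeps the window-level decay log-log
#'   linear), plus a `"fragends"` attribute (list of member fragend
#'   positions per window).
#' @export
window_fragends <- function(fragmap, chrom, bait_pos, k = 8L, region = 1e6,
                            exclude_bait = TRUE) {
  grid <- fragmap$fragends[[chrom]]
  if (is.null(grid)) stop("chromosome not in FragmentMap: ", chrom)
  fe <- grid[abs(grid - bait_pos) <= region]
  if (exclude_bait) fe <- setdiff(fe, bait_fragends(fragmap, chrom, bait_pos))
  nwin <- length(fe) %/% k
  if (nwin == 0L) stop("no complete window of ", k, " fragends near bait")
  fe <- fe[seq_len(nwin * k)]
  wid <- rep(seq_len(nwin), each = k)
  members <- split(fe, wid)
  out <- data.frame(
    window = seq_len(nwin),
    chrom = chrom,
    start = vapply(members, min, 0L),
    end = vapply(members, max, 0L),
    n_fragends = k,
    dist = vapply(members, function(f)
      1 / mean(1 / pmax(abs(f - bait_pos), 1)), 0))
  rownames(out) <- NULL
  attr(out, "fragends") <- members
  out
}

# Sum fragend counts into windows: matrix windows x (allele, replicate).
window_counts <- function(tab, windows, alleles, reps) {
  members <- attr(windows, "fragends")
  chrom <- windows$chrom[1]
  out <- array(0, dim = c(nrow(windows), length(alleles), length(reps)),
               dimnames = list(NULL, alleles, reps))
  for (ai in seq_along(alleles)) for (ri in seq_along(reps)) {
    sel <- tab$chrom == chrom & tab$allele == alleles[ai] &
      tab$replicate == reps[ri]
    if (!any(sel)) next
    cnt <- stats::setNames(tab$count[sel], tab$fragend[sel])
    out[, ai, ri] <- vapply(members, function(f)
      sum(cnt[as.character(f)], na.rm = TRUE), 0)
  }
  out
}

#' Call near-bait interaction domains against a distance-decay background
#'
#' Windows of `k` consecutive fragends near the bait are tested against a
#' smooth background: ordinary least squares of `log(window rpm + 1)` on
#' `log(distance to bait)` gives the expected decay; each window's
#' replicate-summed count is then compared with its fitted expectation by a
#' one-sided Poisson test, BH-corrected across windows. Windows exceeding
#' the background at adjusted p < `alpha` are flagged and adjacent flagged
#' windows are merged into domains. This is a deliberately simple, fully
#' specified near-bait caller, not a reproduction of adaptive-window 4C
#' callers.
#'
#' @param tab a `FragendTable` (bait fragends excluded).
#' @param fragmap a `FragmentMap`.
#' @param chrom chromosome.
#' @param bait_pos 0-based bait position.
#' @param allele which allele's counts to test.
#' @param k fragends per window (default 8).
#' @param region near-bait half-width (default 1e6); at least `3 * k`
#'   fragends must fall inside it.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return list with `windows` (per-window table: counts, rpm, expected,
#'   p, adjusted p, flag) and `domains` (merged flagged windows:
#'   `chrom`, `start`, `end`, `n_windows`).
#' @export
call_interaction_domains <- function(tab, fragmap, chrom, bait_pos,
                                     allele, k = 8L, region = 1e6,
                                     alpha = 0.05) {
  win <- window_fragends(fragmap, chrom, bait_pos, k = k, region = region)
  if (nrow(win) * k < 3L * k)
    stop("too few fragends near bait (need >= ", 3L * k, ")")
  reps <- sort(unique(tab$replicate))
  wc <- window_counts(tab, win, allele, reps)
  cnt <- apply(wc, 1, sum)                      # replicate-summed
  total <- sum(tab$count[tab$allele == allele & tab$chrom == chrom])
  if (total == 0L) {
    win$count <- cnt; win$rpm <- 0; win$expected <- 0
    win$p <- NA_real_; win$padj <- NA_real_; win$flagged <- FALSE
    return(list(windows = win,
                domains = data.frame(chrom = character(), start = integer(),
                                     end = integer(), n_windows = integer())))
  }
  rpm <- cnt * 1e6 / total
  fit <- stats::lm(log(rpm + 1) ~ log(win$dist))
  mu_rpm <- pmax(exp(stats::fitted(fit)) - 1, 1e-9)
  mu <- mu_rpm * total / 1e6
  p <- stats::ppois(cnt - 1, mu, lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "BH")
  flagged <- padj < alpha & cnt > mu
  win$count <- cnt; win$rpm <- rpm; win$expected <- mu
  win$p <- p; win$padj <- padj; win$flagged <- flagged
  domains <- merge_flagged_windows(win)
  list(windows = win, domains = domains)
}

# Merge runs of adjacent flagged windows into domain intervals.
merge_flagged_windows <- function(win) {
  f <- which(win$flagged)
  if (length(f) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer()))
  runs <- split(f, cumsum(c(1L, diff(f) != 1L)))
  out <- do.call(rbind, lapply(runs, function(r)
    data.frame(chrom = win$chrom[r[1]], start = min(win$start[r]),
               end = max(win$end[r]), n_windows = length(r))))
  rownames(out) <- NULL
  out
}

#' Paired maternal-vs-paternal differential interaction test
#'
#' Per window of `k` fragends, the maternal and paternal counts of each
#' replicate (which come from the same library, hence are paired) are
#' tested against the library-wide allele balance with a beta-binomial
#' model: the null maternal proportion is the global
#' `sum(m) / sum(m + p)` over all windows, and a single overdispersion is
#' estimated by method of moments from the between-replicate variability
#' within windows, floored at 0 (where the test reduces to an exact
#' binomial test). Two-sided p values are BH-corrected across windows;
#' windows with zero total in all replicates get `NA` p values.
#'
#' @param tab a `FragendTable` with both alleles (bait fragends excluded).
#' @param fragmap a `FragmentMap`.
#' @param chrom chromosome.
#' @param bait_pos 0-based bait position.
#' @param k fragends per window (default 8).
#' @param region near-bait half-width (default 1e6).
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param pseudocount added to summed counts for the log2 ratio.
#' @return an `InteractionCallSet` data.frame: one row per window with
#'   `start`, `end`, per-allele summed counts, `log2_ratio`, `p`, `padj`,
#'   `significant`; the fitted null proportion and overdispersion are in
#'   attributes `null_prop` and `rho`.
#' @export
differential_allelic_interactions <- function(tab, fragmap, chrom, bait_pos,
                                              k = 8L, region = 1e6,
                                              alpha = 0.05, pseudocount = 1) {
  win <- window_fragends(fragmap, chrom, bait_pos, k = k, region = region)
  reps <- sort(unique(tab$replicate))
  wc <- window_counts(tab, win, c("maternal", "paternal"), reps)
  m_rep <- wc[, "maternal", , drop = FALSE]; dim(m_rep) <- c(nrow(win), length(reps))
  p_rep <- wc[, "paternal", , drop = FALSE]; dim(p_rep) <- c(nrow(win), length(reps))
  M <- rowSums(m_rep); P <- rowSums(p_rep); N <- M + P
  if (sum(N) == 0L) stop("no informative counts in any window")
  pi0 <- sum(M) / sum(N)
  rho <- estimate_overdispersion(m_rep, m_rep + p_rep)
  p <- rep(NA_real_, nrow(win))
  nz <- which(N > 0L)
  for (i in nz) p[i] <- betabinom_test_twosided(M[i], N[i], pi0, rho)
  padj <- rep(NA_real_, nrow(win))
  padj[nz] <- stats::p.adjust(p[nz], method = "BH")
  out <- win[, c("window", "chrom", "start", "end")]
  out$maternal <- M; out$paternal <- P
  out$log2_ratio <- log2((M + pseudocount) / (P + pseudocount))
  out$p <- p; out$padj <- padj
  out$significant <- !is.na(padj) & padj < alpha
  attr(out, "null_prop") <- pi0
  attr(out, "rho") <- rho
  attr(out, "fragends") <- attr(win, "fragends")
  class(out) <- c("InteractionCallSet", "data.frame")
  out
}

# Method-of-moments intra-class correlation for beta-binomial counts:
# pooled within-window chi-square of replicate proportions around the
# window mean, converted to rho via phi = 1 + (nbar - 1) rho, floored at 0.
# With a single replicate there is no within-window information: rho = 0.
estimate_overdispersion <- function(m_rep, n_rep) {
  R <- ncol(m_rep)
  if (R < 2L) return(0)
  X <- 0; df <- 0; nsum <- 0; nobs <- 0
  for (w in seq_len(nrow(m_rep))) {
    n <- n_rep[w, ]; m <- m_rep[w, ]
    use <- n > 0L
    if (sum(use) < 2L) next
    pbar <- sum(m[use]) / sum(n[use])
    if (pbar <= 0 || pbar >= 1) next
    X <- X + sum((m[use] - n[use] * pbar)^2 / (n[use] * pbar * (1 - pbar)))
    df <- df + sum(use) - 1L
    nsum <- nsum + sum(n[use]); nobs <- nobs + sum(use)
  }
  if (df == 0L || nobs == 0L) return(0)
  phi <- X / df
  nbar <- nsum / nobs
  if (nbar <= 1) return(0)
  max(0, (phi - 1) / (nbar - 1))
}

# Beta-binomial log pmf with mean pi and intra-class correlation rho.
dbetabinom_log <- function(x, n, pi, rho) {
  if (rho <= 0) return(stats::dbinom(x, n, pi, log = TRUE))
  s <- (1 - rho) / rho
  a <- pi * s; b <- (1 - pi) * s
  lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b)
}

# Two-sided exact test by the minimum-likelihood method (as binom.test):
# sum the probabilities of all outcomes no more likely than the observed.
betabinom_test_twosided <- function(m, n, pi, rho) {
  lp <- dbetabinom_log(0:n, n, pi, rho)
  obs <- lp[m + 1L]
  min(1, sum(exp(lp[lp <= obs + 1e-7])))
}
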