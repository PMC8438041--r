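#' Configuration for a synthetic virome community
#'
#' Defines the study conditions emulated by [gen_community()]: viral and host
#' genome counts and sizes, CRISPR array content planted into host genomes,
#' the per-sample abundance model (log-normal with a forced core subset of
#' genera), and Hi-C contact structure.
#'
#' @param n_viruses Number of viral genomes (contigs).
#' @param n_hosts Number of prokaryotic host genomes.
#' @param n_samples Number of samples in the abundance model.
#' @param virus_len_range Length range (bp) for viral genomes.
#' @param host_len Host genome length (bp).
#' @param genes_per_kb Gene density used to annotate contigs.
#' @param spacers_per_host Number of CRISPR spacers planted per host genome
#'   (one array per genome); each spacer is sampled from a viral genome.
#' @param spacer_len_range Planted spacer length range (bp). Must lie within
#'   `[19, 48]` so the planted arrays are detectable under the default
#'   repeat/spacer detector parameters.
#' @param repeat_len CRISPR repeat length (bp), within `[19, 38]`.
#' @param subs_per_spacer Number of substitutions applied to each planted
#'   spacer relative to its viral source (0 = exact protospacer copies).
#' @param core_fraction Fraction of viral genera forced present in every
#'   sample (the shared "core" of the community).
#' @param abundance_sigma Log-scale standard deviation of the log-normal
#'   genus abundance draws.
#' @param hic_true_contacts Hi-C contact count planted on each true
#'   virus-host pair.
#' @param hic_noise_contacts Total number of background Hi-C contacts spread
#'   uniformly over random virus-host pairs.
#' @param n_reads_per_sample Optional number of error-free 150-bp reads to
#'   emit per sample (0 = none); used by the toy mapper and rarefaction.
#' @param dataset_size Nominal dataset size (bp) per sample used to scale
#'   the coverage table.
#' @param seed Integer seed; fully determines all generator output.
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_viruses = 50, n_hosts = 30, n_samples = 3,
                         virus_len_range = c(8000L, 20000L),
                         host_len = 30000L, genes_per_kb = 1,
                         spacers_per_host = 3L,
                         spacer_len_range = c(25L, 45L),
                         repeat_len = 28L, subs_per_spacer = 0L,
                         core_fraction = 0.5, abundance_sigma = 1.5,
                         hic_true_contacts = 20L, hic_noise_contacts = 50L,
                         n_reads_per_sample = 0L, dataset_size = 1e8,
                         seed = 1L) {
  cfg <- list(n_viruses = as.integer(n_viruses),
              n_hosts = as.integer(n_hosts),
              n_samples = as.integer(n_samples),
              virus_len_range = as.integer(virus_len_range),
              host_len = as.integer(host_len),
              genes_per_kb = genes_per_kb,
              spacers_per_host = as.integer(spacers_per_host),
              spacer_len_range = as.integer(spacer_len_range),
              repeat_len = as.integer(repeat_len),
              subs_per_spacer = as.integer(subs_per_spacer),
              core_fraction = core_fraction,
              abundance_sigma = abundance_sigma,
              hic_true_contacts = as.integer(hic_true_contacts),
              hic_noise_contacts = as.integer(hic_noise_contacts),
              n_reads_per_sample = as.integer(n_reads_per_sample),
              dataset_size = dataset_size,
              seed = as.integer(seed))
  counts <- c("n_viruses", "n_hosts", "n_samples", "spacers_per_host",
              "subs_per_spacer", "hic_true_contacts", "hic_noise_contacts",
              "n_reads_per_sample")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0)
      stop(sprintf("'%s' must be a non-negative count", nm))
  }
  if (cfg$spacer_len_range[1] < 19L || cfg$spacer_len_range[2] > 48L ||
      cfg$spacer_len_range[1] > cfg$spacer_len_range[2])
    stop("'spacer_len_range' must lie within [19, 48]: planted arrays ",
         "would be undetectable under default detector parameters")
  if (cfg$repeat_len < 19L || cfg$repeat_len > 38L)
    stop("'repeat_len' must lie within [19, 38]")
  if (cfg$virus_len_range[1] < 1000L)
    stop("'virus_len_range' minimum must be >= 1000 bp")
  if (cfg$core_fraction < 0 || cfg$core_fraction > 1)
    stop("'core_fraction' must be in [0, 1]")
  class(cfg) <- "synth_config"
  cfg
}

#' Apply a fixed number of substitutions to a sequence
#'
#' Substituted positions are chosen without replacement and every
#' substituted base differs from the original, so the output has Hamming
#' distance exactly `n_subs` from the input.
#'
#' @param seq Uppercase ACGT string.
#' @param n_subs Number of substitutions; must not exceed `nchar(seq)`.
#' @param seed Optional seed applied locally (the global RNG state is
#'   restored afterwards); `NULL` uses the current stream.
#' @return Mutated sequence of the same length.
#' @export
mutate_sequence <- function(seq, n_subs, seed = NULL) {
  n <- nchar(seq)
  n_subs <- as.integer(n_subs)
  if (n_subs > n) stop("n_subs exceeds sequence length")
  if (n_subs == 0) return(seq)
  with_seed(seed, {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    pos <- sample.int(n, n_subs)
    bases <- c("A", "C", "G", "T")
    for (i in pos) {
      chars[i] <- sample(setdiff(bases, chars[i]), 1)
    }
    paste(chars, collapse = "")
  })
}

#' Insert a CRISPR repeat-spacer array into a genome
#'
#' Builds `repeat + s1 + repeat + s2 + ... + repeat` (k spacers flanked by
#' k + 1 repeat copies) and inserts it at a 0-based offset.
#'
#' @param genome Background genome sequence.
#' @param repeat_seq Repeat unit sequence.
#' @param spacers Character vector of at least two spacer sequences.
#' @param position 0-based insertion offset in `[0, nchar(genome)]`.
#' @return The genome with the array inserted; total length is the input
#'   length plus the inserted length.
#' @export
plant_crispr_array <- function(genome, repeat_seq, spacers, position) {
  if (length(spacers) < 2)
    stop("need at least 2 spacers (>= 3 repeat copies when flanked)")
  position <- as.integer(position)
  if (position < 0 || position > nchar(genome))
    stop("position out of range")
  insert <- paste0(repeat_seq,
                   paste(vapply(spacers, function(s) paste0(s, repeat_seq),
                                character(1)), collapse = ""))
  paste0(substr(genome, 1, position), insert,
         substr(genome, position + 1, nchar(genome)))
}

# TRUE when a planted array has an unambiguous maximal-repeat decomposition:
# not all bases immediately left of each repeat copy agree, and not all
# bases immediately right agree. Otherwise an exact detector would extend
# the repeat across the planted boundary.
array_boundary_unambiguous <- function(left_flank, spacers, right_flank) {
  lefts <- c(left_flank, substr(spacers, nchar(spacers), nchar(spacers)))
  rights <- c(substr(spacers, 1, 1), right_flank)
  length(unique(lefts)) > 1 && length(unique(rights)) > 1
}

#' Generate a synthetic virome community with planted ground truth
#'
#' Emits viral genomes carrying genes, host genomes carrying CRISPR arrays
#' whose spacers are copied (optionally with substitutions) from the viral
#' genomes, gene-annotation and taxonomy hit tables, a per-sample coverage
#' table following a log-normal genus abundance model with a forced core
#' subset, a Hi-C contact table concentrating counts on true virus-host
#' pairs, and a machine-readable truth bundle.
#'
#' @param cfg A [synth_config()] object.
#' @return A list of class `synth_community` with elements `viruses`,
#'   `hosts` (named sequence vectors), `proteins`, `gene_map`, `annotation`,
#'   `taxhits`, `host_lineage`, `function_table`, `coverage`, `reads`,
#'   `hic`, `bin_membership`, `samples`, and `truth` (the truth bundle:
#'   `true_links`, `true_genus_of`, `true_abundance`, `planted_spacers`,
#'   `planted_arrays`).
#' @export
gen_community <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  samples <- sprintf("s%d", seq_len(cfg$n_samples))

  ## viral genomes
  nv <- cfg$n_viruses
  virus_ids <- if (nv > 0) sprintf("vir%03d", seq_len(nv)) else character(0)
  vlen <- if (nv > 0)
    sample(cfg$virus_len_range[1]:cfg$virus_len_range[2], nv, replace = TRUE)
  else integer(0)
  viruses <- stats::setNames(vapply(vlen, random_dna, character(1)), virus_ids)

  ## genus partition of viruses (sizes 1-3)
  genus_of <- character(0)
  if (nv > 0) {
    sizes <- integer(0)
    while (sum(sizes) < nv) {
      sizes <- c(sizes, sample(1:3, 1, prob = c(0.4, 0.35, 0.25)))
    }
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - nv)
    sizes <- sizes[sizes > 0]
    genus_idx <- rep(seq_along(sizes), times = sizes)
    genus_of <- stats::setNames(sprintf("genus_%02d", genus_idx), virus_ids)
  }
  genera <- unique(unname(genus_of))

  ## genes and proteins: per-genus pools so same-genus viruses share content
  gene_rows <- list()
  proteins <- character(0)
  if (nv > 0) {
    n_genes_v <- pmax(6L, as.integer(round(vlen / 1000 * cfg$genes_per_kb)))
    for (g in seq_along(genera)) {
      members <- which(genus_of == genera[g])
      pool_n <- ceiling(1.5 * max(n_genes_v[members]))
      pool <- vapply(sample(80:200, pool_n, replace = TRUE),
                     random_protein, character(1))
      names(pool) <- sprintf("%s_p%02d", genera[g], seq_len(pool_n))
      for (vi in members) {
        pick <- sort(sample.int(pool_n, n_genes_v[vi]))
        gid <- sprintf("%s_g%02d", virus_ids[vi], seq_along(pick))
        proteins[gid] <- unname(pool[pick])
        gene_rows[[length(gene_rows) + 1L]] <-
          data.frame(gene_id = gid, contig_id = virus_ids[vi],
                     stringsAsFactors = FALSE)
      }
    }
  }
  gene_map <- if (length(gene_rows)) do.call(rbind, gene_rows)
  else data.frame(gene_id = character(0), contig_id = character(0))

  ## host genomes and lineages
  nh <- cfg$n_hosts
  host_ids <- if (nh > 0) sprintf("host%03d", seq_len(nh)) else character(0)
  hosts <- stats::setNames(
    vapply(rep(cfg$host_len, nh), random_dna, character(1)), host_ids)
  host_lineage <- data.frame(genome_id = character(0), domain = character(0),
                             phylum = character(0), class = character(0),
                             order = character(0), family = character(0),
                             genus = character(0), stringsAsFactors = FALSE)
  if (nh > 0) {
    n_hg <- max(1L, ceiling(0.7 * nh))
    hg_idx <- sort(c(seq_len(n_hg), sample.int(n_hg, nh - n_hg, replace = TRUE)))
    hg_idx <- hg_idx[sample.int(nh)]  # shuffle genus sharing across hosts
    dom <- ifelse(seq_len(n_hg) <= max(1L, round(0.15 * n_hg)),
                  "Archaea", "Bacteria")
    host_lineage <- data.frame(
      genome_id = host_ids,
      domain = dom[hg_idx],
      phylum = sprintf("%s_phy%02d", dom[hg_idx], (hg_idx %% 7) + 1L),
      class = sprintf("cls%02d", (hg_idx %% 9) + 1L),
      order = sprintf("ord%02d", (hg_idx %% 11) + 1L),
      family = sprintf("fam%02d", hg_idx),
      genus = sprintf("hgen%02d", hg_idx),
      stringsAsFactors = FALSE)
  }

  ## MIDAS-style genus -> function table
  fun_pool <- c("P-removal", "S-reduction", "Nitrification",
                "Methanogenesis", "C-degradation", "Fermentation")
  function_table <- data.frame(genus = character(0), func = character(0),
                               stringsAsFactors = FALSE)
  if (nh > 0) {
    hgen <- unique(host_lineage$genus)
    ft <- lapply(hgen, function(g) {
      k <- sample(1:2, 1)
      data.frame(genus = g, func = sample(fun_pool, k),
                 stringsAsFactors = FALSE)
    })
    function_table <- do.call(rbind, ft)
  }

  ## plant CRISPR arrays: spacers sampled from viral genomes
  planted <- list()
  planted_arrays <- list()
  repeat_of <- stats::setNames(
    vapply(seq_len(nh), function(i) random_dna(cfg$repeat_len), character(1)),
    host_ids)
  if (nh > 0 && nv > 0 && cfg$spacers_per_host >= 2) {
    for (h in host_ids) {
      k <- cfg$spacers_per_host
      pos <- sample(1000:(cfg$host_len - 1000), 1)
      left_flank <- substr(hosts[[h]], pos, pos)
      right_flank <- substr(hosts[[h]], pos + 1, pos + 1)
      for (try in seq_len(200)) {
        src <- sample(virus_ids, k, replace = TRUE)
        slen <- sample(cfg$spacer_len_range[1]:cfg$spacer_len_range[2], k,
                       replace = TRUE)
        sstart <- vapply(seq_len(k), function(i)
          sample.int(nchar(viruses[[src[i]]]) - slen[i] + 1L, 1), integer(1))
        orig <- vapply(seq_len(k), function(i)
          substr(viruses[[src[i]]], sstart[i], sstart[i] + slen[i] - 1L),
          character(1))
        spc <- vapply(orig, function(s)
          mutate_sequence(s, min(cfg$subs_per_spacer, nchar(s))),
          character(1), USE.NAMES = FALSE)
        if (array_boundary_unambiguous(left_flank, spc, right_flank)) break
      }
      hosts[[h]] <- plant_crispr_array(hosts[[h]], repeat_of[[h]], spc, pos)
      rl <- cfg$repeat_len
      sp_start0 <- pos + rl + c(0L, cumsum(nchar(spc) + rl))[seq_len(k)]
      planted[[h]] <- data.frame(
        host_id = h, spacer_seq = spc, source_virus_id = src,
        n_substitutions = pmin(cfg$subs_per_spacer, nchar(orig)),
        source_start = sstart - 1L, source_end = sstart - 1L + slen,
        start = sp_start0, end = sp_start0 + nchar(spc),
        stringsAsFactors = FALSE)
      planted_arrays[[h]] <- data.frame(
        host_id = h, repeat_seq = repeat_of[[h]], n_repeats = k + 1L,
        start = pos, stringsAsFactors = FALSE)
    }
  }
  planted_spacers <- if (length(planted)) do.call(rbind, planted)
  else data.frame(host_id = character(0), spacer_seq = character(0),
                  source_virus_id = character(0),
                  n_substitutions = integer(0), source_start = integer(0),
                  source_end = integer(0), start = integer(0),
                  end = integer(0), stringsAsFactors = FALSE)
  rownames(planted_spacers) <- NULL
  planted_arrays <- if (length(planted_arrays)) do.call(rbind, planted_arrays)
  else data.frame(host_id = character(0), repeat_seq = character(0),
                  n_repeats = integer(0), start = integer(0),
                  stringsAsFactors = FALSE)
  rownames(planted_arrays) <- NULL

  ## true virus-host links
  if (nrow(planted_spacers) > 0) {
    lk <- unique(planted_spacers[, c("source_virus_id", "host_id")])
    true_links <- data.frame(
      virus_id = lk$source_virus_id, host_id = lk$host_id,
      host_genus = host_lineage$genus[match(lk$host_id,
                                            host_lineage$genome_id)],
      stringsAsFactors = FALSE)
    true_links <- true_links[order(true_links$virus_id, true_links$host_id), ]
    rownames(true_links) <- NULL
  } else {
    true_links <- data.frame(virus_id = character(0), host_id = character(0),
                             host_genus = character(0),
                             stringsAsFactors = FALSE)
  }

  ## gene annotation hit table (viral + host contigs)
  ann <- list()
  if (nrow(gene_map) > 0) {
    spl <- split(gene_map$gene_id, gene_map$contig_id)
    for (v in names(spl)) {
      gid <- spl[[v]]
      ng <- length(gid)
      n_vpf <- ceiling(0.85 * ng)
      ann[[v]] <- data.frame(
        gene_id = gid, contig_id = v,
        has_vpf = seq_len(ng) <= n_vpf,
        has_pfam = seq_len(ng) <= round(0.2 * ng),
        has_ko = seq_len(ng) <= round(0.05 * ng),
        bitscore = round(stats::runif(ng, 50, 500), 1),
        lineage = "Viruses;Caudovirales",
        stringsAsFactors = FALSE)
    }
  }
  for (h in host_ids) {
    ng <- as.integer(round(cfg$host_len / 1000 * cfg$genes_per_kb))
    lin <- host_lineage[host_lineage$genome_id == h, ]
    ann[[h]] <- data.frame(
      gene_id = sprintf("%s_g%02d", h, seq_len(ng)), contig_id = h,
      has_vpf = FALSE,
      has_pfam = seq_len(ng) <= round(0.7 * ng),
      has_ko = seq_len(ng) <= round(0.6 * ng),
      bitscore = round(stats::runif(ng, 50, 500), 1),
      lineage = paste(lin$domain, lin$phylum, sep = ";"),
      stringsAsFactors = FALSE)
  }
  annotation <- if (length(ann)) do.call(rbind, ann)
  else data.frame(gene_id = character(0), contig_id = character(0),
                  has_vpf = logical(0), has_pfam = logical(0),
                  has_ko = logical(0), bitscore = numeric(0),
                  lineage = character(0), stringsAsFactors = FALSE)
  rownames(annotation) <- NULL

  ## taxonomy hits for the LCA route
  fam <- c("Podoviridae", "Siphoviridae", "Myoviridae")
  th <- list()
  for (v in virus_ids) {
    f <- sample(fam, 1)
    nhit <- sample(2:3, 1)
    th[[v]] <- data.frame(
      contig_id = v,
      lineage = paste("Viruses", "Caudovirales", f,
                      sprintf("%s_sp%02d", f, sample(1:20, nhit, replace = TRUE)),
                      sep = ";"),
      bitscore = round(stats::runif(nhit, 200, 400), 1),
      stringsAsFactors = FALSE)
  }
  for (h in host_ids) {
    lin <- host_lineage[host_lineage$genome_id == h, ]
    th[[h]] <- data.frame(
      contig_id = h,
      lineage = paste(lin$domain, lin$phylum, lin$class, sep = ";"),
      bitscore = round(stats::runif(1, 200, 400), 1),
      stringsAsFactors = FALSE)
  }
  taxhits <- if (length(th)) do.call(rbind, th)
  else data.frame(contig_id = character(0), lineage = character(0),
                  bitscore = numeric(0), stringsAsFactors = FALSE)
  rownames(taxhits) <- NULL

  ## abundance model: log-normal genus draws, forced core subset
  S <- cfg$n_samples
  true_abundance <- matrix(0, nrow = length(genera), ncol = S,
                           dimnames = list(genera, samples))
  virus_ab <- matrix(0, nrow = nv, ncol = S,
                     dimnames = list(virus_ids, samples))
  if (nv > 0 && S > 0) {
    n_core <- max(1L, round(cfg$core_fraction * length(genera)))
    core <- sort(sample(genera, n_core))
    raw <- matrix(exp(stats::rnorm(length(genera) * S, 0,
                                   cfg$abundance_sigma)),
                  nrow = length(genera), dimnames = list(genera, samples))
    for (g in genera) {
      if (!(g %in% core) && S > 1) {
        nz <- sample.int(S - 1L, 1)           # absent from >= 1 sample
        raw[g, sample.int(S, nz)] <- 0
      }
    }
    true_abundance <- sweep(raw, 2, colSums(raw), "/")
    w <- stats::setNames(exp(stats::rnorm(nv, 0, 0.5)), virus_ids)
    for (g in genera) {
      members <- virus_ids[genus_of == g]
      wm <- w[members] / sum(w[members])
      virus_ab[members, ] <- outer(wm, raw[g, ])
    }
    virus_ab <- sweep(virus_ab, 2, colSums(virus_ab), "/")
    attr(true_abundance, "core_genera") <- core
  }

  ## coverage table (aligned bases per contig per sample)
  dataset_size <- round(cfg$dataset_size * stats::runif(S, 0.8, 1.2))
  cov <- NULL
  if (nv > 0 && S > 0) {
    depth_scale <- 3e4
    cov <- do.call(rbind, lapply(seq_len(S), function(s) {
      data.frame(contig_id = virus_ids, sample_id = samples[s],
                 aligned_bases = round(depth_scale * virus_ab[, s] * vlen),
                 dataset_size = dataset_size[s], stringsAsFactors = FALSE)
    }))
    rownames(cov) <- NULL
  } else {
    cov <- data.frame(contig_id = character(0), sample_id = character(0),
                      aligned_bases = numeric(0), dataset_size = numeric(0),
                      stringsAsFactors = FALSE)
  }

  ## optional error-free 150-bp reads per sample
  reads <- NULL
  if (cfg$n_reads_per_sample > 0 && nv > 0) {
    reads <- lapply(seq_len(S), function(s) {
      p <- virus_ab[, s] * vlen
      if (sum(p) == 0) return(stats::setNames(character(0), character(0)))
      src <- sample(virus_ids, cfg$n_reads_per_sample, replace = TRUE,
                    prob = p / sum(p))
      starts <- vapply(src, function(v)
        sample.int(nchar(viruses[[v]]) - 150L + 1L, 1), integer(1))
      r <- vapply(seq_along(src), function(i)
        substr(viruses[[src[i]]], starts[i], starts[i] + 149L), character(1))
      stats::setNames(r, sprintf("%s_r%05d", samples[s], seq_along(r)))
    })
    names(reads) <- samples
  }

  ## Hi-C contact table: fixed counts on true pairs + uniform noise
  bin_membership <- data.frame(genome_id = host_ids,
                               bin_id = sprintf("bin_%s", host_ids),
                               stringsAsFactors = FALSE)
  hic <- data.frame(virus_id = character(0), bin_id = character(0),
                    count = integer(0), stringsAsFactors = FALSE)
  if (nrow(true_links) > 0) {
    hic <- data.frame(
      virus_id = true_links$virus_id,
      bin_id = sprintf("bin_%s", true_links$host_id),
      count = cfg$hic_true_contacts, stringsAsFactors = FALSE)
  }
  if (cfg$hic_noise_contacts > 0 && nv > 0 && nh > 0) {
    nz <- data.frame(
      virus_id = sample(virus_ids, cfg$hic_noise_contacts, replace = TRUE),
      bin_id = sprintf("bin_%s",
                       sample(host_ids, cfg$hic_noise_contacts,
                              replace = TRUE)),
      stringsAsFactors = FALSE)
    agg <- stats::aggregate(list(count = rep(1L, nrow(nz))),
                            nz[, c("virus_id", "bin_id")], sum)
    hic <- rbind(hic, agg)
    hic <- stats::aggregate(list(count = hic$count),
                            hic[, c("virus_id", "bin_id")], sum)
  }
  hic <- hic[order(hic$virus_id, hic$bin_id), ]
  rownames(hic) <- NULL

  structure(list(
    cfg = cfg, samples = samples,
    viruses = viruses, hosts = hosts,
    proteins = proteins, gene_map = gene_map,
    annotation = annotation, taxhits = taxhits,
    host_lineage = host_lineage, function_table = function_table,
    coverage = cov, reads = reads,
    hic = hic, bin_membership = bin_membership,
    truth = list(true_links = true_links,
                 true_genus_of = genus_of,
                 true_abundance = true_abundance,
                 planted_spacers = planted_spacers,
                 planted_arrays = planted_arrays,
                 planted_repeats = repeat_of)),
    class = "synth_community")
}

#' Write a synthetic community to disk
#'
#' Writes standard multi-FASTA files and header-rowed TSV tables (all
#' coordinates 0-based half-open), including the truth bundle.
#'
#' @param comm A `synth_community` from [gen_community()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of written file paths.
#' @export
write_community <- function(comm, dir) {
  stopifnot(inherits(comm, "synth_community"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  out <- c(
    viruses = write_fasta(comm$viruses, p("viruses.fasta")),
    hosts = write_fasta(comm$hosts, p("hosts.fasta")),
    proteins = write_fasta(comm$proteins, p("proteins.faa"), type = "AA"),
    gene_map = write_tsv(comm$gene_map, p("gene_map.tsv")),
    annotation = write_tsv(comm$annotation, p("annotation.tsv")),
    taxhits = write_tsv(comm$taxhits, p("taxhits.tsv")),
    host_lineage = write_tsv(comm$host_lineage, p("host_lineage.tsv")),
    function_table = write_tsv(comm$function_table, p("function_table.tsv")),
    coverage = write_tsv(comm$coverage, p("coverage.tsv")),
    hic = write_tsv(comm$hic, p("hic_contacts.tsv")),
    bin_membership = write_tsv(comm$bin_membership, p("bin_membership.tsv")),
    true_links = write_tsv(comm$truth$true_links, p("truth_links.tsv")),
    true_genus = write_tsv(
      data.frame(virus_id = names(comm$truth$true_genus_of),
                 genus = unname(comm$truth$true_genus_of)),
      p("truth_genus.tsv")),
    true_abundance = write_tsv(
      data.frame(genus = rownames(comm$truth$true_abundance),
                 comm$truth$true_abundance, check.names = FALSE),
      p("truth_abundance.tsv")),
    planted_spacers = write_tsv(comm$truth$planted_spacers,
                                p("planted_spacers.tsv")))
  if (!is.null(comm$reads)) {
    for (s in names(comm$reads)) {
      out[paste0("reads_", s)] <-
        write_fasta(comm$reads[[s]], p(sprintf("reads_%s.fasta", s)))
    }
  }
  invisible(out)
}
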