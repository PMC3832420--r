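# Deterministic synthetic alignment/read generators. These stand in for the
# benchmark accessions in every test: the codec never inspects reference
# biology, only record structure, so i.i.d. nucleotides and parametric event
# rates are adequate. Identical spec + seed => identical output.

#' Specify a synthetic alignment fixture
#'
#' The parameters describe the statistics of an aligned sequencing dataset:
#' sample size, read length, pairing and insert-size distribution, splice
#' rate, per-base substitution and indel rates, soft-clip rate, the fraction
#' of consecutive duplicate templates (PCR-duplicate analogue, the driver of
#' template compression), and sortedness. Defaults emulate a sorted
#' paired-end spliced RNA-Seq alignment; see the preset constructors for the
#' other dataset classes.
#'
#' @param n_entries number of alignment entries to generate (exact).
#' @param read_length read length in bases.
#' @param n_targets,target_length reference dictionary shape.
#' @param paired generate mate pairs with reciprocal pair links.
#' @param insert_mean,insert_sd insert size distribution (bases).
#' @param spliced allow spliced fragments connected by splice links.
#' @param splice_rate fraction of mates that are spliced in two fragments.
#' @param intron_min,intron_max intron length bounds (bases).
#' @param substitution_rate per-base substitution probability.
#' @param indel_rate per-read indel probability.
#' @param softclip_rate per-entry soft-clip probability.
#' @param duplicate_rate probability that a unit duplicates the previous
#'   unit's position and template fields.
#' @param bisulfite emulate bisulfite conversion (C-to-T substitutions).
#' @param quality_mode `"variation"` stores quality bytes on variations
#'   only; `"all"` additionally stores all aligned base qualities
#'   (`to_quality`); `"none"` stores no qualities.
#' @param unknown_field_rate fraction of entries carrying a synthetic
#'   unknown-field payload (schema-evolution fixtures).
#' @param sorted sort entries by (target, position).
#' @param seed RNG seed; the generator restores the caller's RNG state.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_entries = 1000L, read_length = 100L,
                         n_targets = 2L, target_length = 1000000L,
                         paired = FALSE, insert_mean = 300, insert_sd = 30,
                         spliced = FALSE, splice_rate = 0.25,
                         intron_min = 60L, intron_max = 5000L,
                         substitution_rate = 0.005, indel_rate = 0.001,
                         softclip_rate = 0.02, duplicate_rate = 0.15,
                         bisulfite = FALSE, quality_mode = c("variation", "all", "none"),
                         unknown_field_rate = 0, sorted = TRUE, seed = 1L) {
  quality_mode <- match.arg(quality_mode)
  rates <- c(splice_rate, substitution_rate, indel_rate, softclip_rate,
             duplicate_rate, unknown_field_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (n_entries < 0) stop("n_entries must be non-negative")
  structure(as.list(environment()), class = "fixture_spec")
}

#' Fixture presets for the benchmark dataset classes
#'
#' Four parameterizations emulating the statistics of the assay types used
#' to benchmark structured alignment compression: spliced paired RNA-Seq,
#' exome capture, whole-genome sequencing, and reduced-representation
#' bisulfite sequencing (RRBS; restriction-site anchored, hence highly
#' duplicated start positions).
#'
#' @param n_entries entries per fixture.
#' @param seed RNG seed.
#' @export
fixture_rnaseq <- function(n_entries = 1000L, seed = 1L) {
  fixture_spec(n_entries = n_entries, paired = TRUE, spliced = TRUE,
               splice_rate = 0.3, substitution_rate = 0.004,
               duplicate_rate = 0.2, seed = seed)
}

#' @rdname fixture_rnaseq
#' @export
fixture_exome <- function(n_entries = 1000L, seed = 1L) {
  fixture_spec(n_entries = n_entries, paired = TRUE, spliced = FALSE,
               substitution_rate = 0.01, indel_rate = 0.002,
               softclip_rate = 0.05, duplicate_rate = 0.15,
               target_length = 200000L, seed = seed)
}

#' @rdname fixture_rnaseq
#' @export
fixture_wgs <- function(n_entries = 1000L, seed = 1L) {
  fixture_spec(n_entries = n_entries, paired = TRUE, spliced = FALSE,
               substitution_rate = 0.001, indel_rate = 0.001,
               softclip_rate = 0.01, duplicate_rate = 0.05,
               target_length = 5000000L, seed = seed)
}

#' @rdname fixture_rnaseq
#' @export
fixture_rrbs <- function(n_entries = 1000L, seed = 1L) {
  fixture_spec(n_entries = n_entries, paired = FALSE, spliced = FALSE,
               substitution_rate = 0.04, bisulfite = TRUE,
               duplicate_rate = 0.5, target_length = 100000L,
               read_length = 75L, seed = seed)
}

BASES <- c("A", "C", "G", "T")

with_fixture_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

random_bases <- function(n) {
  if (n <= 0) return("")
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# substitutions planted on one aligned segment; bisulfite biases toward C>T
plant_variations <- function(spec, span, read_offset, qmode) {
  k <- rbinom(1, spec$read_length, spec$substitution_rate)
  k <- min(k, span)
  if (k == 0) return(list())
  at <- sort(sample.int(span, k))
  out <- vector("list", k)
  for (j in seq_len(k)) {
    if (spec$bisulfite && runif(1) < 0.8) {
      from <- "C"; to <- "T"
    } else {
      from <- sample(BASES, 1)
      to <- sample(setdiff(BASES, from), 1)
    }
    out[[j]] <- sequence_variation(
      position = at[j] - 1L, read_index = read_offset + at[j],
      from = from, to = to,
      to_quality = if (qmode == "none") NULL else
        sample.int(40, 1) + 2L)
  }
  out
}

plant_indel <- function(spec, span, read_offset) {
  if (runif(1) >= spec$indel_rate || span < 10) return(list())
  at <- sample.int(span - 5L, 1) + 2L
  len <- sample.int(3L, 1)
  if (runif(1) < 0.5) {
    list(sequence_variation(position = at - 1L, read_index = read_offset + at,
                            from = "", to = random_bases(len)))
  } else {
    list(sequence_variation(position = at - 1L, read_index = read_offset + at,
                            from = random_bases(len), to = ""))
  }
}

#' Generate a synthetic alignment collection
#'
#' Produces `spec$n_entries` alignment entries satisfying all data-model
#' invariants, together with the matching [alignment_header()]. Paired specs
#' produce consistent reciprocal pair links; spliced mates are split in two
#' fragments connected by forward/backward splice links. Query indices are a
#' random permutation of read ordinals (read order differs from genomic
#' order, as after sorting a real alignment).
#'
#' @param spec a [fixture_spec()].
#' @return `list(entries, header)`.
#' @export
generate_alignment_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_rng(spec$seed, {
    n <- spec$n_entries
    header <- alignment_header(
      target_names = paste0("chr", seq_len(spec$n_targets)),
      target_lengths = rep(spec$target_length, spec$n_targets),
      sorted = spec$sorted)
    if (n == 0) return(list(entries = list(), header = header))

    units <- list()      # each unit: the entries of one read (mates + frags)
    built <- 0L
    prev_unit <- NULL
    qi_next <- 0L
    while (built < n) {
      remaining <- n - built
      dup <- !is.null(prev_unit) && runif(1) < spec$duplicate_rate &&
        length(prev_unit$entries) <= remaining
      if (dup) {
        unit <- duplicate_unit(prev_unit, qi_next)
      } else {
        paired <- spec$paired && remaining >= 2L
        unit <- make_unit(spec, paired, remaining, qi_next)
      }
      qi_next <- qi_next + 1L
      units[[length(units) + 1L]] <- unit
      built <- built + length(unit$entries)
      prev_unit <- unit
    }
    entries <- unlist(lapply(units, `[[`, "entries"), recursive = FALSE)

    # genomic sort, then resolve link triples (they were built from the
    # planted coordinates, which sorting does not change)
    if (spec$sorted) {
      ord <- order(vnum(entries, "target_index"), vnum(entries, "position"),
                   vnum(entries, "fragment_index"))
      entries <- entries[ord]
    }
    nreads <- max(vnum(entries, "query_index")) + 1L
    perm <- sample.int(nreads) - 1L
    for (i in seq_along(entries)) {
      entries[[i]]$query_index <- perm[entries[[i]]$query_index + 1L]
      if (spec$unknown_field_rate > 0 && runif(1) < spec$unknown_field_rate) {
        payload <- make_unknown_payload(
          100L, as.raw(sample.int(256, sample.int(16, 1)) - 1L))
        entries[[i]]$unknown_fields <- payload
      }
    }
    header$n_queries <- as.integer(nreads)
    list(entries = entries, header = header)
  })
}

make_unit <- function(spec, paired, budget, qi) {
  qmode <- spec$quality_mode
  ti <- sample.int(spec$n_targets, 1) - 1L
  ql <- spec$read_length
  span_max <- max(1L, spec$target_length - 3L * (spec$intron_max + ql))
  pos1 <- sample.int(span_max, 1) - 1L

  mk_mate <- function(pos, strand, frag_base, budget_frags) {
    # one mate: either a single entry or two spliced fragments
    clip_l <- if (runif(1) < spec$softclip_rate) sample.int(8L, 1) else 0L
    clip_r <- if (runif(1) < spec$softclip_rate) sample.int(8L, 1) else 0L
    qal <- ql - clip_l - clip_r
    spliced <- spec$spliced && budget_frags >= 2L && runif(1) < spec$splice_rate
    segs <- if (spliced) {
      l1 <- sample.int(qal - 20L, 1) + 10L
      list(c(l1, qal - l1))[[1]]
    } else qal
    intron <- if (spliced) sample(spec$intron_min:spec$intron_max, 1) else 0L
    out <- vector("list", length(segs))
    p <- pos
    roff <- clip_l
    for (s in seq_along(segs)) {
      span <- segs[s]
      vars <- c(plant_variations(spec, span, roff, qmode),
                plant_indel(spec, span, roff))
      e <- alignment_entry(
        query_index = qi, target_index = ti, position = p,
        fragment_index = frag_base + s - 1L,
        matching_reverse_strand = strand,
        query_length = ql, query_aligned_length = span,
        target_aligned_length = span,
        mapping_quality = sample(c(0L, 20L, 30L, 37L, 60L), 1,
                                 prob = c(.02, .05, .13, .3, .5)),
        score = as_float32(sample.int(200L, 1)),
        sequence_variations = vars)
      if (s == 1 && clip_l > 0) {
        e$softclip_left <- random_bases(clip_l)
        if (qmode != "none")
          e$softclip_left_quality <- sample.int(40, clip_l, replace = TRUE) + 2L
      }
      if (s == length(segs) && clip_r > 0) {
        e$softclip_right <- random_bases(clip_r)
        if (qmode != "none")
          e$softclip_right_quality <- sample.int(40, clip_r, replace = TRUE) + 2L
      }
      if (qmode == "all")
        e$to_quality <- sample.int(40, span, replace = TRUE) + 2L
      out[[s]] <- e
      p <- p + span + intron
      roff <- roff + span
    }
    # splice links between consecutive fragments
    if (length(out) == 2) {
      out[[1]]$splice_forward_link <- entry_link(
        position = out[[2]]$position, target_index = ti,
        fragment_index = out[[2]]$fragment_index)
      out[[2]]$splice_backward_link <- entry_link(
        position = out[[1]]$position, target_index = ti,
        fragment_index = out[[1]]$fragment_index)
    }
    out
  }

  if (paired) {
    insert <- max(2L * ql, as.integer(round(rnorm(1, spec$insert_mean, spec$insert_sd))))
    pos2 <- pos1 + insert - ql
    budget_m1 <- max(1L, budget - 2L)   # keep room for mate 2
    m1 <- mk_mate(pos1, FALSE, 0L, budget_m1)
    m2 <- mk_mate(pos2, TRUE, length(m1), budget - length(m1) - 1L)
    m1[[1]]$pair_link <- entry_link(position = m2[[1]]$position,
                                    target_index = ti,
                                    fragment_index = m2[[1]]$fragment_index)
    m2[[1]]$pair_link <- entry_link(position = m1[[1]]$position,
                                    target_index = ti,
                                    fragment_index = m1[[1]]$fragment_index)
    list(entries = c(m1, m2))
  } else {
    list(entries = mk_mate(pos1, runif(1) < 0.5, 0L, budget))
  }
}

duplicate_unit <- function(unit, qi) {
  # PCR-duplicate analogue: same coordinates and template fields, new read
  unit$entries <- lapply(unit$entries, function(e) {
    e$query_index <- qi
    e
  })
  unit
}
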