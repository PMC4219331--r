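#' Configuration for the synthetic two-organism benchmark
#'
#' Builds and validates the configuration for [generate_benchmark()]. The
#' generator emulates the statistical structure the annotation-transfer
#' benchmark assumes: several families descended from common ancestors, two
#' organisms whose members diverge independently from each ancestor, substrate
#' labels that cross-cut family labels, and optionally planted sequence
#' motifs.
#'
#' @param n_families Number of families.
#' @param members_per_family Members per family per organism; a single count
#'   or a length-2 range sampled uniformly per family.
#' @param seq_length Ancestor length; a single value or a length-2 range.
#' @param substitution_rate Per-site substitution probability on each lineage,
#'   in `[0, 1)`. A substituted site is redrawn from the background
#'   distribution excluding its current residue.
#' @param indel_rate Per-site probability that an indel event starts, in
#'   `[0, 1)`.
#' @param indel_length_geometric_p Success parameter of the geometric indel
#'   length distribution (support 1, 2, ...), in `(0, 1]`.
#' @param background Length-20 amino-acid frequency vector summing to 1,
#'   named by residue; default uniform.
#' @param substrate_plan Named list mapping substrate-class labels to integer
#'   family indices; families may appear under several substrates, which is
#'   what makes substrate labels cross-cut family labels. The default plan
#'   assigns every family two substrate classes in a cyclic design.
#' @param motif_plan Optional list of motif specs, each a list with elements
#'   `family` (index), `consensus` (string over the 20-letter alphabet) and
#'   `conservation` (per-position retention probability in `(0, 1]`).
#' @param organisms Length-2 character vector of organism names.
#' @param seed Integer seed; all randomness in [generate_benchmark()] flows
#'   from it.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_families = 4,
                              members_per_family = 5,
                              seq_length = 400,
                              substitution_rate = 0.1,
                              indel_rate = 0.01,
                              indel_length_geometric_p = 0.5,
                              background = uniform_background(),
                              substrate_plan = default_substrate_plan(n_families),
                              motif_plan = NULL,
                              organisms = c("OrgA", "OrgB"),
                              seed = 42L) {
  stopifnot(n_families >= 1, all(members_per_family >= 1),
            length(members_per_family) %in% c(1, 2),
            all(seq_length >= 1), length(seq_length) %in% c(1, 2),
            length(organisms) == 2)
  if (substitution_rate < 0 || substitution_rate >= 1) abort("substitution_rate must be in [0, 1)")
  if (indel_rate < 0 || indel_rate >= 1) abort("indel_rate must be in [0, 1)")
  if (indel_length_geometric_p <= 0 || indel_length_geometric_p > 1) {
    abort("indel_length_geometric_p must be in (0, 1]")
  }
  background <- validate_background(background)
  if (length(substrate_plan) > 0) {
    idx <- unlist(substrate_plan)
    if (any(idx < 1 | idx > n_families)) abort("substrate_plan indices must be in 1..n_families")
  }
  for (m in motif_plan) {
    stopifnot(m$family >= 1, m$family <= n_families)
    validate_aa(m$consensus, "motif consensus")
    if (m$conservation <= 0 || m$conservation > 1) abort("motif conservation must be in (0, 1]")
  }
  structure(list(n_families = as.integer(n_families),
                 members_per_family = as.integer(members_per_family),
                 seq_length = as.integer(seq_length),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 indel_length_geometric_p = indel_length_geometric_p,
                 background = background,
                 substrate_plan = substrate_plan,
                 motif_plan = motif_plan,
                 organisms = organisms,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname simulation_config
#' @export
uniform_background <- function() {
  setNames(rep(1 / 20, 20), AA_ALPHABET20)
}

#' Membrane-protein-like background frequencies
#'
#' A hydrophobic-enriched amino-acid background (roughly doubling the weight
#' of A, F, G, I, L, M, V, W) motivated by the distinctive residue
#' composition of membrane transporters. Not the default; useful for checking
#' sensitivity of results to background composition.
#'
#' @return Named length-20 frequency vector summing to 1.
#' @export
membrane_background <- function() {
  w <- setNames(rep(1, 20), AA_ALPHABET20)
  w[c("A", "F", "G", "I", "L", "M", "V", "W")] <- 2
  w / sum(w)
}

validate_background <- function(background) {
  if (is.null(names(background))) names(background) <- AA_ALPHABET20
  stopifnot(length(background) == 20, setequal(names(background), AA_ALPHABET20))
  background <- background[AA_ALPHABET20]
  if (abs(sum(background) - 1) > 1e-9) abort("background frequencies must sum to 1")
  background
}

default_substrate_plan <- function(n_families) {
  subs <- c("metal", "phosphate", "sugar", "amino_acid")
  if (n_families < 2) return(list(metal = 1L))
  # cyclic cross-cutting design: substrate s covers families {s, s+1} mod n
  plan <- lapply(seq_len(min(4, n_families)), function(s) {
    c(s, s %% n_families + 1L)
  })
  setNames(plan, subs[seq_along(plan)])
}

#' Draw a random protein sequence from a background distribution
#'
#' @param length Sequence length.
#' @param background Length-20 frequency vector (see [uniform_background()]).
#' @return A single uppercase sequence string.
#' @export
random_protein <- function(length, background = uniform_background()) {
  background <- validate_background(background)
  paste(sample(AA_ALPHABET20, length, replace = TRUE, prob = background), collapse = "")
}

#' Mutate a protein sequence under a substitution/indel model
#'
#' Each site is substituted independently with probability
#' `substitution_rate`; the replacement is drawn from `background` with the
#' current residue excluded, so at rate 1 no site retains its original
#' residue. Indel events start at each site with probability `indel_rate`;
#' each event is an insertion or a deletion with equal probability and has
#' geometric length (support 1, 2, ...). If deletions would remove the whole
#' sequence, one residue is retained (the output is never empty).
#'
#' @inheritParams simulation_config
#' @param seq Input sequence string.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (as when called from [generate_benchmark()]).
#' @return The mutated sequence string.
#' @export
mutate_sequence <- function(seq, substitution_rate, indel_rate = 0,
                            indel_length_geometric_p = 0.5,
                            background = uniform_background(), seed = NULL) {
  if (!nzchar(seq)) abort("cannot mutate an empty sequence")
  background <- validate_background(background)
  run <- function() {
    chars <- strsplit(seq, "")[[1]]
    n <- length(chars)
    # substitutions
    if (substitution_rate > 0) {
      hit <- which(runif(n) < substitution_rate)
      for (i in hit) {
        p <- background
        if (chars[i] %in% names(p)) p[chars[i]] <- 0
        chars[i] <- sample(AA_ALPHABET20, 1, prob = p / sum(p))
      }
    }
    # indels: process event sites from right to left so indices stay valid
    if (indel_rate > 0) {
      sites <- which(runif(n) < indel_rate)
      for (i in rev(sites)) {
        len <- stats::rgeom(1, indel_length_geometric_p) + 1L
        if (runif(1) < 0.5) {
          ins <- sample(AA_ALPHABET20, len, replace = TRUE, prob = background)
          chars <- append(chars, ins, after = i - 1L)
        } else {
          drop <- i:min(length(chars), i + len - 1L)
          if (length(drop) >= length(chars)) drop <- drop[-1]  # keep one residue
          if (length(drop) > 0) chars <- chars[-drop]
        }
        if (length(chars) == 0) chars <- sample(AA_ALPHABET20, 1, prob = background)
      }
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Plant a motif instance into a sequence
#'
#' Replaces the window starting at 0-based `position` by the motif consensus,
#' with each consensus position independently retained with probability
#' `conservation` and otherwise redrawn from the background.
#'
#' @inheritParams mutate_sequence
#' @param consensus Motif consensus string.
#' @param conservation Per-position retention probability in `(0, 1]`.
#' @param position 0-based start of the planted window.
#' @return The sequence with the motif planted.
#' @export
plant_motif <- function(seq, consensus, conservation, position,
                        background = uniform_background(), seed = NULL) {
  w <- nchar(consensus)
  n <- nchar(seq)
  if (position < 0 || position + w > n) {
    abort(paste0("motif window [", position, ", ", position + w,
                 ") out of range for sequence of length ", n))
  }
  background <- validate_background(background)
  run <- function() {
    site <- strsplit(consensus, "")[[1]]
    redraw <- which(runif(w) >= conservation)
    for (i in redraw) {
      site[i] <- sample(AA_ALPHABET20, 1, prob = background)
    }
    paste0(substr(seq, 1, position), paste(site, collapse = ""),
           substr(seq, position + w + 1, n))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a synthetic two-organism benchmark with ground truth
#'
#' For each family one ancestor sequence is drawn from the background
#' distribution; every member in each organism is produced from that ancestor
#' by one independent pass of [mutate_sequence()], so two members diverge
#' through two independent lineages. Families carry synthetic TC labels
#' (`"2.A.1"`, `"2.A.2"`, ...), substrate labels follow the configured
#' substrate plan, and motifs are planted per the motif plan (at a uniformly
#' drawn valid position per member, after mutation, so a planted motif's
#' conservation is controlled exactly).
#'
#' @param config A [simulation_config()] object.
#' @return A list with `dataset_a`, `dataset_b` (annotated dataset tibbles,
#'   see [annotated_dataset()]), `truth` (tibble: `id`, `organism`, `family`,
#'   `substrates`, `ancestor`, `motif_start`, `motif_end` with 0-based
#'   half-open motif coordinates, `NA` when no motif was planted) and
#'   `config`. Deterministic given `config$seed`.
#' @export
generate_benchmark <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_benchmark_impl(config))
}

generate_benchmark_impl <- function(config) {
  fam_labels <- sprintf("2.A.%d", seq_len(config$n_families))
  fam_substrates <- vapply(seq_len(config$n_families), function(k) {
    subs <- names(config$substrate_plan)[vapply(config$substrate_plan,
                                                function(v) k %in% v, logical(1))]
    paste(sort(subs), collapse = ",")
  }, character(1))

  pick <- function(x) if (length(x) == 2) sample(seq(x[1], x[2]), 1) else x

  rows <- list()
  truths <- list()
  for (k in seq_len(config$n_families)) {
    anc_len <- pick(config$seq_length)
    ancestor <- random_protein(anc_len, config$background)
    anc_id <- sprintf("F%02d_anc", k)
    motifs_k <- Filter(function(m) m$family == k, config$motif_plan %||% list())
    for (org_i in 1:2) {
      org <- config$organisms[org_i]
      n_members <- pick(config$members_per_family)
      for (j in seq_len(n_members)) {
        s <- mutate_sequence(ancestor, config$substitution_rate, config$indel_rate,
                             config$indel_length_geometric_p, config$background)
        mstart <- NA_integer_; mend <- NA_integer_
        for (m in motifs_k) {
          w <- nchar(m$consensus)
          if (w <= nchar(s)) {
            pos <- sample(0:(nchar(s) - w), 1)
            s <- plant_motif(s, m$consensus, m$conservation, pos, config$background)
            mstart <- pos; mend <- pos + w
          }
        }
        id <- sprintf("%s_F%02d_M%02d", org, k, j)
        rows[[length(rows) + 1L]] <- tibble(
          id = id, organism = org, sequence = s,
          tc_family = fam_labels[k], substrates = fam_substrates[k])
        truths[[length(truths) + 1L]] <- tibble(
          id = id, organism = org, family = fam_labels[k],
          substrates = fam_substrates[k], ancestor = anc_id,
          motif_start = mstart, motif_end = mend)
      }
    }
  }
  all_rows <- dplyr::bind_rows(rows)
  truth <- dplyr::bind_rows(truths)
  split_org <- function(org) {
    ds <- dplyr::filter(all_rows, .data$organism == org)
    attr(ds, "organism") <- org
    attr(ds, "residue_count") <- residue_count(ds)
    ds
  }
  list(dataset_a = split_org(config$organisms[1]),
       dataset_b = split_org(config$organisms[2]),
       truth = truth,
       config = config)
}
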