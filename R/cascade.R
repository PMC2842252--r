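# The iterative subtraction analysis across two species:
# TATAWA -> TATA variants at Hamming distance 1/2/3 -> dinucleotides ->
# exhaustive hexamer scan of the TA-less sets, plus the exclusive
# promoter classification.

# ---------------------------------------------------------------------------
# per-species scanning state: a k-mer position index built once on the full
# set, plus the active-promoter mask updated as the cascade subtracts.

.datatable.aware <- TRUE

.kmer_index <- function(set, k) {
  n <- length(set)
  lens <- nchar(set$seq)
  nk <- pmax(lens - k + 1L, 0L)
  kmers <- vector("list", n)
  for (i in seq_len(n)) {
    if (nk[i] == 0L) { kmers[[i]] <- character(0); next }
    st <- seq_len(nk[i])
    kmers[[i]] <- substring(set$seq[i], st, st + k - 1L)
  }
  dt <- data.table::data.table(
    kmer = unlist(kmers, use.names = FALSE),
    prom = rep.int(seq_len(n), nk),
    pos = unlist(lapply(nk, seq_len), use.names = FALSE) - set$upstream - 1L)
  data.table::setkey(dt, kmer)
  dt
}

.state_new <- function(set, config, k = 6L) {
  list(set = set, config = config, k = k,
       idx = .kmer_index(set, k),
       dmax = set$downstream - 1L,
       active = rep(TRUE, length(set)))
}

# occurrences of a concrete k-mer (k == state$k) among active promoters
.state_occ <- function(state, motif) {
  kmer <- NULL  # data.table NSE
  hit <- state$idx[.(motif), nomatch = NULL]
  keep <- state$active[hit$prom]
  list(prom = hit$prom[keep], pos = hit$pos[keep], k = state$k, motif = motif)
}

# detect one motif in the current (active) promoters; motifs of length
# != state$k (patterns, dinucleotides) fall back to string matching
.state_detect <- function(state, motif) {
  members <- expand_pattern(motif)
  if (all(nchar(members) == state$k)) {
    if (length(members) == 1L) occ <- .state_occ(state, members)
    else {
      parts <- lapply(members, .state_occ, state = state)
      prom <- unlist(lapply(parts, `[[`, "prom"), use.names = FALSE)
      pos <- unlist(lapply(parts, `[[`, "pos"), use.names = FALSE)
      o <- order(prom, pos)
      occ <- list(prom = prom[o], pos = pos[o], k = state$k)
    }
  } else {
    sub <- .subset_set(state$set, state$active)
    occ0 <- .occ(sub, motif)
    # map back to full-set promoter indices
    full <- which(state$active)
    occ <- list(prom = full[occ0$prom], pos = occ0$pos, k = occ0$k)
  }
  occ$motif <- toupper(motif)
  tryCatch(.plm_core(occ, state$dmax, state$set$ids, state$config),
           plm_zero_denominator = function(e) NULL)
}

# remove active promoters carrying `motif` (concrete or pattern) with a
# first base inside the window; returns the removed ids
.state_remove <- function(state, motif, window) {
  members <- expand_pattern(motif)
  rm_prom <- integer(0)
  for (m in members) {
    if (nchar(m) == state$k) occ <- .state_occ(state, m)
    else {
      sub <- .subset_set(state$set, state$active)
      occ0 <- .occ(sub, m)
      full <- which(state$active)
      occ <- list(prom = full[occ0$prom], pos = occ0$pos)
    }
    keep <- occ$pos >= window[1] & occ$pos <= window[2]
    rm_prom <- c(rm_prom, occ$prom[keep])
  }
  unique(rm_prom)
}

# ---------------------------------------------------------------------------

# scan a motif list in both species; accept motifs that are PLMs in both
# with the preferential position inside the target region
.conserved_scan <- function(state_a, state_b, motifs, config) {
  accepted <- character(0)
  rec_a <- list(); rec_b <- list()
  for (m in motifs) {
    ra <- .state_detect(state_a, m)
    if (!plm_in_region(ra, config$target)) next
    rb <- .state_detect(state_b, m)
    if (!plm_in_region(rb, config$target)) next
    accepted <- c(accepted, m)
    rec_a[[m]] <- ra; rec_b[[m]] <- rb
  }
  list(accepted = accepted, rec_a = rec_a, rec_b = rec_b)
}

#' Run the motif discovery cascade on two promoter sets
#'
#' Reproduces the iterative subtraction analysis. Stage 1 detects the
#' canonical TATA-box (pattern `TATAWA`) in each species and subtracts the
#' promoters carrying it within its detected functional window. Stage 2
#' scans, for Hamming distances d = 1, 2, 3 from the TATAWA expansion, the
#' distance-d motif ring on the current (subtracted) sets, accepting motifs
#' that are PLMs in both species with a preferential position inside
#' `config$target`, and subtracting their promoters before the next d.
#' Stage 3 scans the 16 dinucleotides the same way. Stage 4 scans all 4096
#' hexamers on the resulting TA-less sets; conserved PLMs positioned in the
#' target region are reported as TC-element candidates. All motifs are
#' accepted simultaneously per stage and their promoters subtracted at once,
#' so within-stage ordering is immaterial.
#'
#' @param set_a,set_b `promoter_set` objects for the two species.
#' @param config A [scan_config()].
#' @return An object of class `plm_cascade`: accepted motif vectors
#'   (`tatawa`, `tata_delta` by distance, `dinucleotides`, `tc_elements`),
#'   per-species `plm_record`s per accepted motif, the subtraction ledger
#'   (`stage`, `species`, `before`, `removed`, `after`), and the remaining
#'   (TA-less) promoter ids per species.
#' @export
run_cascade <- function(set_a, set_b, config = scan_config()) {
  stopifnot(inherits(set_a, "promoter_set"), inherits(set_b, "promoter_set"))
  st <- list(a = .state_new(set_a, config), b = .state_new(set_b, config))
  ledger <- data.frame(stage = character(), species = character(),
                       before = integer(), removed = integer(),
                       after = integer(), stringsAsFactors = FALSE)
  records <- list(a = list(), b = list())
  note_ledger <- function(stage, removed) {
    for (sp in c("a", "b")) {
      before <- sum(st[[sp]]$active) + length(removed[[sp]])
      ledger[nrow(ledger) + 1L, ] <<- list(stage, st[[sp]]$set$species,
                                           before, length(removed[[sp]]),
                                           sum(st[[sp]]$active))
    }
  }
  run_stage <- function(stage, motifs) {
    if (!sum(st$a$active) || !sum(st$b$active))
      return(character(0))
    sc <- .conserved_scan(st$a, st$b, motifs, config)
    removed <- list(a = integer(0), b = integer(0))
    for (m in sc$accepted) {
      records$a[[m]] <<- sc$rec_a[[m]]
      records$b[[m]] <<- sc$rec_b[[m]]
      removed$a <- union(removed$a,
                         .state_remove(st$a, m, sc$rec_a[[m]]$functional_window))
      removed$b <- union(removed$b,
                         .state_remove(st$b, m, sc$rec_b[[m]]$functional_window))
    }
    st$a$active[removed$a] <<- FALSE
    st$b$active[removed$b] <<- FALSE
    note_ledger(stage, removed)
    sc$accepted
  }

  tatawa <- run_stage("tatawa", "TATAWA")
  tata_delta <- list()
  for (d in 1:3)
    tata_delta[[as.character(d)]] <-
      run_stage(paste0("tata_delta", d), hamming_ring("TATAWA", d))
  dinucs <- run_stage("dinucleotides", expand_pattern("NN"))
  # stage 4: exhaustive hexamer scan of the TA-less sets (no subtraction)
  tc <- if (sum(st$a$active) && sum(st$b$active)) {
    sc <- .conserved_scan(st$a, st$b, expand_pattern("NNNNNN"), config)
    for (m in sc$accepted) {
      records$a[[m]] <- sc$rec_a[[m]]
      records$b[[m]] <- sc$rec_b[[m]]
    }
    sc$accepted
  } else character(0)

  structure(list(
    tatawa = tatawa,
    tata_delta = tata_delta,
    dinucleotides = dinucs,
    tc_elements = tc,
    records = records,
    ledger = ledger,
    ta_less_ids = list(a = set_a$ids[st$a$active], b = set_b$ids[st$b$active]),
    species = c(a = set_a$species, b = set_b$species),
    config = config), class = "plm_cascade")
}

#' @export
print.plm_cascade <- function(x, ...) {
  cat("PLM discovery cascade\n")
  cat(sprintf("  stage 1 TATAWA:        %s\n",
              if (length(x$tatawa)) "detected in both species" else "not detected"))
  for (d in names(x$tata_delta))
    cat(sprintf("  stage 2 TATA-delta %s:  %d motif(s) %s\n", d,
                length(x$tata_delta[[d]]),
                paste(x$tata_delta[[d]], collapse = " ")))
  cat(sprintf("  stage 3 dinucleotides: %d motif(s) %s\n",
              length(x$dinucleotides), paste(x$dinucleotides, collapse = " ")))
  cat(sprintf("  stage 4 TC candidates: %d motif(s) %s\n",
              length(x$tc_elements), paste(x$tc_elements, collapse = " ")))
  cat(sprintf("  TA-less promoters: %d (%s) / %d (%s)\n",
              length(x$ta_less_ids$a), x$species["a"],
              length(x$ta_less_ids$b), x$species["b"]))
  invisible(x)
}

#' Exclusive promoter classification by core-promoter element class
#'
#' Each promoter is tested for the presence, with a first base inside
#' `config$target`, of (i) any TATAWA expansion motif, (ii) any accepted
#' TATA-variant motif, (iii) any accepted TC-element. Promoters matching
#' exactly one class receive the corresponding `*_only` label; none:
#' `plm_less`; two or more: `multi_class` (excluded from every "only" set).
#'
#' @param set A `promoter_set` (one of the species the cascade ran on).
#' @param cascade A `plm_cascade`.
#' @param config A [scan_config()].
#' @return An object of class `plm_classification`: a data.frame (`id`,
#'   `tata`, `tatad`, `tc`, `label`) plus a `counts` attribute.
#' @export
classify_promoters <- function(set, cascade, config = scan_config()) {
  stopifnot(inherits(set, "promoter_set"), inherits(cascade, "plm_cascade"))
  target <- config$target
  has_class <- function(motifs) {
    out <- rep(FALSE, length(set))
    for (m in motifs) {
      occ <- .occ(set, m)
      keep <- occ$pos >= target[1] & occ$pos <= target[2]
      out[unique(occ$prom[keep])] <- TRUE
    }
    out
  }
  tata <- has_class("TATAWA")
  tatad <- has_class(unlist(cascade$tata_delta, use.names = FALSE))
  tc <- has_class(cascade$tc_elements)
  nclass <- tata + tatad + tc
  label <- rep("plm_less", length(set))
  label[nclass >= 2L] <- "multi_class"
  label[nclass == 1L & tata] <- "tata_only"
  label[nclass == 1L & tatad] <- "tatad_only"
  label[nclass == 1L & tc] <- "tc_only"
  df <- data.frame(id = set$ids, tata = tata, tatad = tatad, tc = tc,
                   label = label, stringsAsFactors = FALSE)
  counts <- table(factor(label, levels = c("tata_only", "tatad_only",
                                           "tc_only", "plm_less",
                                           "multi_class")))
  structure(df, class = c("plm_classification", "data.frame"),
            counts = counts)
}

#' @export
print.plm_classification <- function(x, ...) {
  cat("Exclusive promoter classification:\n")
  print(attr(x, "counts"))
  invisible(x)
}
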