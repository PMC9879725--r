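#' Read a reference sequence from FASTA or raw text
#'
#' Accepts either a FASTA file (first record is used; a warning is issued if
#' more are present) or a raw text file containing the sequence, possibly
#' line-wrapped. The sequence is uppercased and validated.
#'
#' @param path Path to the file.
#' @return The reference sequence as a single string.
#' @export
read_reference <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort_varalg(sprintf("reference file not found: %s", path), "varalg_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort_varalg(sprintf("reference file is empty: %s", path), "varalg_io_error")
  }
  if (startsWith(trimws(lines[1L]), ">")) {
    rlang::check_installed("Biostrings", reason = "to read FASTA references")
    recs <- Biostrings::readBStringSet(path)
    if (length(recs) == 0L) {
      abort_varalg(sprintf("no FASTA record in %s", path), "varalg_io_error")
    }
    if (length(recs) > 1L) {
      rlang::warn(sprintf("%s has %d FASTA records; using the first (%s)",
                          path, length(recs), names(recs)[1L]))
    }
    seq <- as.character(recs[[1L]])
  } else {
    seq <- paste(lines, collapse = "")
  }
  check_sequence(seq, "reference", allow_empty = FALSE)
}

#' Read a plain-text variant list
#'
#' One variant per line, either `HGVS` or `ID<TAB>HGVS`; `#` comment lines
#' and blank lines are skipped. Ids default to line numbers. Parse errors
#' are reported with their line numbers and are fatal by default;
#' `skip_invalid = TRUE` logs a warning per bad line and continues (keeping
#' only the interpretable variants).
#'
#' @param path Path to the list file.
#' @param reference The reference sequence (or its length) used to validate
#'   positions.
#' @param skip_invalid Skip unparseable lines with a warning instead of
#'   failing.
#' @return A tibble with columns `id`, `text` and `rep` (list of
#'   [variant_rep]).
#' @export
read_variant_list <- function(path, reference, skip_invalid = FALSE) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort_varalg(sprintf("variant list not found: %s", path), "varalg_io_error")
  }
  ref_len <- if (is.numeric(reference)) as.integer(reference) else
    nchar(check_sequence(reference, "reference"))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  line_no <- which(keep)
  lines <- trimws(lines[keep])
  ids <- character(0); texts <- character(0); reps <- list()
  for (t in seq_along(lines)) {
    fields <- strsplit(lines[t], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (length(fields) >= 2L) {
      id <- fields[1L]; text <- fields[2L]
    } else {
      id <- as.character(line_no[t]); text <- fields[1L]
    }
    rep <- tryCatch(parse_variant(text, ref_len), varalg_error = function(e) e)
    if (inherits(rep, "condition")) {
      msg <- sprintf("line %d (\"%s\"): %s", line_no[t], text, conditionMessage(rep))
      if (skip_invalid) {
        rlang::warn(paste("skipping", msg))
        next
      }
      abort_varalg(msg, class(rep)[1L])
    }
    ids <- c(ids, id); texts <- c(texts, text); reps <- c(reps, list(rep))
  }
  tibble::tibble(id = ids, text = texts, rep = reps)
}

#' Read variants from a VCF file (experimental)
#'
#' Thin adapter turning `POS`/`REF`/`ALT` records into delins
#' representations on original reference coordinates. Multi-allelic records
#' are split into one variant per alternate allele; symbolic alleles and
#' breakends are rejected. Coordinates are used as-is (the VCF must be
#' called against the same reference sequence passed to the comparison
#' functions). Experimental: no normalisation or validation against the
#' reference sequence is performed beyond position ranges.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @param reference_length Reference length for position validation.
#' @return A tibble with columns `id`, `text` and `rep`.
#' @export
read_vcf_variants <- function(path, reference_length) {
  rlang::check_installed("vcfR", reason = "to read VCF files")
  if (!file.exists(path)) {
    abort_varalg(sprintf("VCF not found: %s", path), "varalg_io_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- character(0); texts <- character(0); reps <- list()
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(unname(fix[r, "ALT"]), ",", fixed = TRUE)[[1]]
    ref <- toupper(unname(fix[r, "REF"]))
    pos <- as.integer(fix[r, "POS"])
    for (ai in seq_along(alts)) {
      alt <- toupper(alts[ai])
      if (grepl("[<>\\[\\]*.]", alt)) {
        abort_varalg(sprintf("symbolic/breakend allele not supported: %s", alt),
                     "varalg_unsupported_error")
      }
      to <- pos + nchar(ref) - 1L
      text <- if (nchar(ref) == 1L && nchar(alt) == 1L) {
        sprintf("%d%s>%s", pos, ref, alt)
      } else if (pos == to) {
        sprintf("%ddelins%s", pos, alt)
      } else {
        sprintf("%d_%ddelins%s", pos, to, alt)
      }
      id <- unname(fix[r, "ID"])
      if (is.na(id) || id == ".") id <- sprintf("%s:%d", unname(fix[r, "CHROM"]), pos)
      if (length(alts) > 1L) id <- sprintf("%s/%d", id, ai)
      ids <- c(ids, id)
      texts <- c(texts, text)
      reps <- c(reps, list(parse_variant(text, reference_length)))
    }
  }
  tibble::tibble(id = ids, text = texts, rep = reps)
}

# Normalise the accepted variant-collection forms to tibble(id, rep, observed).
normalize_variants <- function(reference, variants) {
  if (is.data.frame(variants)) {
    ids <- if ("id" %in% names(variants)) as.character(variants$id) else
      as.character(seq_len(nrow(variants)))
    reps <- if ("rep" %in% names(variants)) variants$rep else
      as.list(variants$text)
  } else {
    if (!is.list(variants)) variants <- as.list(variants)
    ids <- names(variants)
    if (is.null(ids) || any(!nzchar(ids))) {
      auto <- as.character(seq_along(variants))
      ids <- if (is.null(ids)) auto else ifelse(nzchar(ids), ids, auto)
    }
    reps <- variants
  }
  observed <- unname(vapply(reps, function(v) resolve_observed(reference, v),
                            character(1)))
  if (any(observed == reference)) {
    abort_varalg(
      sprintf("empty variant(s): %s (observed sequence equals the reference)",
              paste(ids[observed == reference], collapse = ", ")),
      "varalg_empty_variant_error"
    )
  }
  tibble::tibble(id = ids, rep = reps, observed = observed)
}

#' All-pairs Boolean relations over a variant set
#'
#' Computes the relation for every unordered pair of variants against one
#' reference. With the prefilter (default), each variant's maximal
#' influence interval is computed once and pairs whose intervals do not
#' intersect are emitted as `"disjoint"` without any alignment work; the
#' remaining candidate pairs are classified with the full comparison.
#' Element sets are computed lazily and cached per variant. Prefiltered and
#' unfiltered runs produce identical records.
#'
#' @param reference Reference sequence.
#' @param variants A tibble from [read_variant_list()] (columns `id`,
#'   `rep`), or a (named) list/vector of representations, descriptions or
#'   [observed()] sequences.
#' @param use_prefilter Use the interval prefilter.
#' @return A `relation_records` tibble with one row per unordered pair
#'   (upper triangle; converse relations are not duplicated): `lhs_id`,
#'   `rhs_id`, `relation`, and the two intervals' bounds. [glance()] gives
#'   the per-relation counts, [relation_degrees()] the per-variant
#'   non-disjoint degree distribution.
#' @examples
#' run_all_pairs("TCCCTTTA",
#'               c(O = "3C>A", P = "6T>G", P1 = "[4del;5_6insC]", P2 = "2_3insT"))
#' @export
run_all_pairs <- function(reference, variants, use_prefilter = TRUE) {
  reference <- check_sequence(reference, "reference", allow_empty = FALSE)
  tbl <- normalize_variants(reference, variants)
  n <- nrow(tbl)
  graphs <- lapply(tbl$observed, function(o) build_lcs_graph(reference, o))
  ivs <- lapply(graphs, influence_interval)
  dR <- vapply(graphs, `[[`, integer(1), "distance")
  psis <- vector("list", n) # lazily filled Psi key cache
  psi_of <- function(t) {
    if (is.null(psis[[t]])) psis[[t]] <<- psi_keys(graphs[[t]])
    psis[[t]]
  }
  m <- (n * (n - 1L)) %/% 2L
  li <- integer(m); ri <- integer(m); rel <- character(m)
  r <- 0L
  for (x in seq_len(max(n - 1L, 0L))) {
    for (y in seq.int(x + 1L, n)) {
      r <- r + 1L
      li[r] <- x; ri[r] <- y
      if (use_prefilter && !intervals_intersect(ivs[[x]], ivs[[y]])) {
        rel[r] <- "disjoint"
        next
      }
      O <- tbl$observed[x]; P <- tbl$observed[y]
      rel[r] <- if (O == P) {
        "equivalent"
      } else {
        dOP <- wave_core(O, P)$distance
        if (dR[x] - dR[y] == dOP) "contains"
        else if (dR[y] - dR[x] == dOP) "is_contained"
        else if (dR[x] + dR[y] == dOP) "disjoint"
        else if (any(psi_of(x) %in% psi_of(y))) "overlap"
        else "disjoint"
      }
    }
  }
  records <- tibble::tibble(
    lhs_id = tbl$id[li], rhs_id = tbl$id[ri], relation = rel,
    lhs_interval_start = vapply(ivs[li], `[[`, integer(1), "start"),
    lhs_interval_end = vapply(ivs[li], `[[`, integer(1), "end"),
    rhs_interval_start = vapply(ivs[ri], `[[`, integer(1), "start"),
    rhs_interval_end = vapply(ivs[ri], `[[`, integer(1), "end")
  )
  class(records) <- c("relation_records", class(records))
  attr(records, "reference") <- reference
  attr(records, "variant_ids") <- tbl$id
  attr(records, "use_prefilter") <- use_prefilter
  records
}

#' Write / read relation records as TSV
#'
#' Seven tab-separated columns with a header line; relation names are the
#' lowercase five-name vocabulary. Reading back reproduces the records.
#'
#' @param records A `relation_records` tibble.
#' @param path Output (input) path.
#' @return `path` invisibly; for the reader, a `relation_records` tibble.
#' @export
write_relations_tsv <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_relations_tsv
#' @export
read_relations_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "character",
                                         "integer", "integer", "integer", "integer"))
  records <- tibble::as_tibble(df)
  bad <- setdiff(unique(records$relation), relation_levels)
  if (length(bad)) {
    abort_varalg(sprintf("unknown relation value(s): %s", paste(bad, collapse = ", ")),
                 "varalg_io_error")
  }
  class(records) <- c("relation_records", class(records))
  attr(records, "variant_ids") <- unique(c(records$lhs_id, records$rhs_id))
  records
}

#' Per-variant non-disjoint degree distribution
#'
#' Counts, for every variant in a record set, the number of other variants
#' it has a non-disjoint relation with.
#'
#' @param records A `relation_records` tibble.
#' @return A tibble with columns `id` and `degree`, including zero-degree
#'   variants.
#' @export
relation_degrees <- function(records) {
  ids <- attr(records, "variant_ids")
  if (is.null(ids)) ids <- unique(c(records$lhs_id, records$rhs_id))
  nd <- records$relation != "disjoint"
  touched <- c(records$lhs_id[nd], records$rhs_id[nd])
  counts <- table(factor(touched, levels = ids))
  tibble::tibble(id = ids, degree = as.integer(counts))
}
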