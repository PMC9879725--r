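#' Variant representations as tibbles of atomic operations
#'
#' A variant representation is an ordered collection of atomic operations —
#' single-symbol deletions and single-symbol insertions — indexed on the
#' *original* coordinates of a reference sequence. Positions are 1-based;
#' an insertion is anchored in the gap *after* a reference position, with
#' anchor 0 denoting an insertion before the first symbol. Deletions may
#' carry the deleted symbol as an (optional, validated) annotation.
#'
#' Representations are stored as tibbles with one row per atomic operation
#' and columns `op` (`"del"` or `"ins"`), `pos` (deletion position or
#' insertion anchor) and `symbol` (inserted symbol; deleted symbol or `NA`).
#' Deletion positions must be pairwise distinct; the relative order of
#' insertion rows sharing an anchor is significant.
#'
#' @param op Character vector of operation kinds, `"del"` or `"ins"`.
#' @param pos Integer vector of deletion positions (1-based) or insertion
#'   anchors (0-based gap after the position).
#' @param symbol Character vector of symbols; required for insertions,
#'   optional annotation for deletions (`NA` to omit).
#' @return A `variant_rep` tibble.
#' @examples
#' variant_rep(c("del", "ins"), c(7L, 8L), c("T", "A"))
#' @export
variant_rep <- function(op = character(), pos = integer(), symbol = NA_character_) {
  n <- length(op)
  pos <- as.integer(pos)
  symbol <- toupper(as.character(symbol))
  if (n > 0L) symbol <- rep_len(symbol, n)
  if (length(pos) != n) {
    abort_varalg("`op` and `pos` must have the same length.", "varalg_type_error")
  }
  if (!all(op %in% c("del", "ins"))) {
    abort_varalg("`op` must be \"del\" or \"ins\".", "varalg_type_error")
  }
  if (anyNA(pos) || any(pos < 0L)) {
    abort_varalg("`pos` must be non-negative integers.", "varalg_range_error")
  }
  if (any(op == "ins" & (is.na(symbol) | !nzchar(symbol)))) {
    abort_varalg("insertions require a `symbol`.", "varalg_type_error")
  }
  if (any(op == "del" & pos == 0L)) {
    abort_varalg("deletion positions are 1-based (position 0 is invalid).",
                 "varalg_range_error")
  }
  if (anyDuplicated(pos[op == "del"])) {
    abort_varalg("deletion positions must be pairwise distinct.", "varalg_range_error")
  }
  new_variant_rep(op, pos, symbol)
}

# Fast internal constructor, no validation.
new_variant_rep <- function(op = character(), pos = integer(), symbol = character()) {
  structure(
    list(op = as.character(op), pos = as.integer(pos), symbol = as.character(symbol)),
    class = c("variant_rep", "tbl_df", "tbl", "data.frame"),
    row.names = c(NA_integer_, -length(op))
  )
}

#' @rdname variant_rep
#' @param x Object to test or coerce.
#' @export
is_variant_rep <- function(x) inherits(x, "variant_rep")

#' Mark a string as an observed sequence
#'
#' Comparison and batch functions accept variants either as HGVS-subset
#' descriptions or as full observed sequences. `observed()` wraps a plain
#' string so it is interpreted as an observed sequence rather than parsed
#' as a description (equivalently, the string may be prefixed `"seq:"`).
#'
#' @param x A single sequence string.
#' @return An `observed_seq` scalar.
#' @examples
#' observed("TG")
#' @export
observed <- function(x) {
  structure(check_sequence(x, "observed"), class = "observed_seq")
}

#' @export
print.observed_seq <- function(x, ...) {
  cat("<observed sequence>", unclass(x), "\n")
  invisible(x)
}

single_op_rx <- list(
  snv    = "^([0-9]+)([A-Za-z])>([A-Za-z])$",
  delins = "^([0-9]+)(?:_([0-9]+))?delins([A-Za-z]+)$",
  del    = "^([0-9]+)(?:_([0-9]+))?del([A-Za-z]*)$",
  ins    = "^([0-9]+)_([0-9]+)ins([A-Za-z]+)$"
)

# Dialect features that exist in full HGVS but are deliberately not
# interpreted here; they must fail loudly, not silently misparse.
unsupported_rx <- "(dup|inv|con|sup|=|\\?|\\(|\\)|\\[[0-9]+\\]|ext|fs)"

parse_single_op <- function(item, reference_length) {
  for (kind in names(single_op_rx)) {
    m <- regmatches(item, regexec(single_op_rx[[kind]], item))[[1]]
    if (length(m) == 0L) next
    m[-1] <- toupper(m[-1])
    if (kind == "snv") {
      p <- as.integer(m[2])
      if (p < 1L || p > reference_length) {
        abort_varalg(sprintf("position %d out of range [1, %d] in \"%s\"",
                             p, reference_length, item), "varalg_range_error")
      }
      return(new_variant_rep(c("del", "ins"), c(p, p), c(m[3], m[4])))
    }
    if (kind == "ins") {
      a <- as.integer(m[2]); b <- as.integer(m[3])
      if (b != a + 1L) {
        abort_varalg(sprintf("insertion \"%s\" must use two flanking positions N_(N+1)",
                             item), "varalg_syntax_error")
      }
      if (a < 0L || a > reference_length) {
        abort_varalg(sprintf("insertion anchor %d out of range [0, %d] in \"%s\"",
                             a, reference_length, item), "varalg_range_error")
      }
      sym <- strsplit(m[4], "")[[1]]
      return(new_variant_rep(rep("ins", length(sym)), rep(a, length(sym)), sym))
    }
    # del / delins
    a <- as.integer(m[2])
    b <- if (is.na(m[3]) || m[3] == "") a else as.integer(m[3])
    if (a > b) {
      abort_varalg(sprintf("range %d_%d is inverted in \"%s\"", a, b, item),
                   "varalg_syntax_error")
    }
    if (a < 1L || b > reference_length) {
      abort_varalg(sprintf("range %d_%d out of range [1, %d] in \"%s\"",
                           a, b, reference_length, item), "varalg_range_error")
    }
    del_pos <- seq.int(a, b)
    if (kind == "del") {
      ann <- m[4]
      del_sym <- rep(NA_character_, length(del_pos))
      if (nzchar(ann)) {
        if (nchar(ann) != length(del_pos)) {
          abort_varalg(sprintf("deleted sequence \"%s\" does not span %d_%d in \"%s\"",
                               ann, a, b, item), "varalg_syntax_error")
        }
        del_sym <- strsplit(ann, "")[[1]]
      }
      return(new_variant_rep(rep("del", length(del_pos)), del_pos, del_sym))
    }
    # delins: deletions a..b plus per-symbol insertions anchored at b. The
    # anchoring is only a starting representation; relations never depend on it.
    ins_sym <- strsplit(m[3 + 1L], "")[[1]]
    return(new_variant_rep(
      c(rep("del", length(del_pos)), rep("ins", length(ins_sym))),
      c(del_pos, rep(b, length(ins_sym))),
      c(rep(NA_character_, length(del_pos)), ins_sym)
    ))
  }
  if (grepl(unsupported_rx, item)) {
    abort_varalg(sprintf("unsupported HGVS feature in \"%s\"", item),
                 "varalg_unsupported_error")
  }
  abort_varalg(sprintf("cannot parse variant description \"%s\"", item),
               "varalg_syntax_error")
}

#' Parse an HGVS-subset variant description
#'
#' Parses the genomic (g.) coordinate subset of HGVS used for small
#' variants: `NdelS?`, `N_MdelS?`, `N_MinsSEQ`, `N_MdelinsSEQ`, `NX>Y`, and
#' bracketed `;`-separated alleles thereof. An SNV `NX>Y` expands to a
#' deletion of position `N` plus an insertion of `Y` anchored at `N`;
#' `N_MdelinsSEQ` expands to deletions `N..M` plus per-symbol insertions of
#' `SEQ` anchored at `M`. Unsupported HGVS features (dup, inv, repeats,
#' uncertain positions, ...) raise an error rather than misparse.
#'
#' @param text A single variant description.
#' @param reference_length Length of the reference sequence; positions are
#'   validated against it (insertion anchors may be 0).
#' @return A [variant_rep] tibble on original reference coordinates.
#' @examples
#' parse_variant("8_9insA", 9)
#' parse_variant("[7delT;8_9insA]", 9)
#' parse_variant("3C>T", 5)
#' @export
parse_variant <- function(text, reference_length) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    abort_varalg("`text` must be a single string.", "varalg_type_error")
  }
  reference_length <- as.integer(reference_length)
  text <- gsub("[[:space:]]", "", text)
  text <- sub("^g\\.", "", text)
  if (!nzchar(text)) {
    return(new_variant_rep())
  }
  items <- text
  if (startsWith(text, "[")) {
    if (!endsWith(text, "]")) {
      abort_varalg(sprintf("unbalanced brackets in \"%s\"", text), "varalg_syntax_error")
    }
    items <- strsplit(substr(text, 2L, nchar(text) - 1L), ";", fixed = TRUE)[[1]]
    if (length(items) == 0L || any(!nzchar(items))) {
      abort_varalg(sprintf("empty allele component in \"%s\"", text), "varalg_syntax_error")
    }
  }
  parts <- lapply(items, parse_single_op, reference_length = reference_length)
  op <- unlist(lapply(parts, `[[`, "op"), use.names = FALSE)
  pos <- unlist(lapply(parts, `[[`, "pos"), use.names = FALSE)
  sym <- unlist(lapply(parts, `[[`, "symbol"), use.names = FALSE)
  if (anyDuplicated(pos[op == "del"])) {
    abort_varalg(sprintf("duplicate deletion position in \"%s\"", text),
                 "varalg_syntax_error")
  }
  new_variant_rep(op, pos, sym)
}

#' Format a representation as an HGVS-subset description
#'
#' The inverse of [parse_variant()]: renders a representation in a canonical
#' textual form. Operations are sorted by position; adjacent runs are
#' collapsed to `del`/`ins`/`delins` shorthand and a single-position
#' deletion-insertion pair with a known deleted symbol is written as an SNV
#' `NX>Y`. A single operation is written without brackets, multiple
#' operations as `[a;b;...]`. The canonical form always patches to the same
#' observed sequence as the input representation.
#'
#' @param rep A [variant_rep].
#' @param reference Optional reference sequence used to annotate deleted
#'   symbols (e.g. to render `1delT` rather than `1del`).
#' @return A single string; the empty representation formats as `""`.
#' @examples
#' format_variant(variant_rep("del", 1), reference = "TTTTTT")
#' format_variant(variant_rep(c("del", "ins"), c(7, 8), c("T", "A")))
#' @export
format_variant <- function(rep, reference = NULL) {
  stopifnot(is_variant_rep(rep))
  if (nrow(rep) == 0L) return("")
  sym <- rep$symbol
  if (!is.null(reference)) {
    reference <- check_sequence(reference, "reference")
    refc <- strsplit(reference, "")[[1]]
    fill <- rep$op == "del" & is.na(sym) & rep$pos <= length(refc)
    sym[fill] <- refc[rep$pos[fill]]
  }
  ord <- order(rep$pos, rep$op == "ins", method = "radix")
  op <- rep$op[ord]; pos <- rep$pos[ord]; sym <- sym[ord]

  groups <- list()
  cur <- NULL # list(del_start, del_end, del_sym, ins_sym, anchor)
  flush <- function(g) {
    if (is.null(g)) return(NULL)
    groups[[length(groups) + 1L]] <<- g
    NULL
  }
  for (t in seq_along(op)) {
    if (op[t] == "del") {
      if (!is.null(cur) && !is.na(cur$del_start) && length(cur$ins_sym) == 0L &&
          pos[t] == cur$del_end + 1L) {
        cur$del_end <- pos[t]
        cur$del_sym <- c(cur$del_sym, sym[t])
      } else {
        cur <- flush(cur)
        cur <- list(del_start = pos[t], del_end = pos[t], del_sym = sym[t],
                    ins_sym = character(), anchor = NA_integer_)
      }
    } else {
      if (!is.null(cur) && !is.na(cur$del_start) && pos[t] == cur$del_end) {
        cur$ins_sym <- c(cur$ins_sym, sym[t])
      } else if (!is.null(cur) && is.na(cur$del_start) && pos[t] == cur$anchor) {
        cur$ins_sym <- c(cur$ins_sym, sym[t])
      } else {
        cur <- flush(cur)
        cur <- list(del_start = NA_integer_, del_end = NA_integer_,
                    del_sym = character(), ins_sym = sym[t], anchor = pos[t])
      }
    }
  }
  flush(cur)

  render <- function(g) {
    if (is.na(g$del_start)) {
      return(sprintf("%d_%dins%s", g$anchor, g$anchor + 1L,
                     paste(g$ins_sym, collapse = "")))
    }
    span <- if (g$del_start == g$del_end) sprintf("%d", g$del_start) else
      sprintf("%d_%d", g$del_start, g$del_end)
    if (length(g$ins_sym) == 0L) {
      ann <- if (anyNA(g$del_sym)) "" else paste(g$del_sym, collapse = "")
      return(paste0(span, "del", ann))
    }
    if (g$del_start == g$del_end && length(g$ins_sym) == 1L && !is.na(g$del_sym[1])) {
      return(sprintf("%d%s>%s", g$del_start, g$del_sym[1], g$ins_sym[1]))
    }
    paste0(span, "delins", paste(g$ins_sym, collapse = ""))
  }
  out <- vapply(groups, render, character(1))
  if (length(out) == 1L) out else paste0("[", paste(out, collapse = ";"), "]")
}

#' Apply a representation to a reference sequence
#'
#' Deterministically transforms the reference into the observed sequence
#' (cf. Unix `patch`): reference symbols at non-deleted positions are
#' emitted in order, with insertions emitted immediately after their anchor
#' position; multiple insertions at one anchor are emitted in row order.
#'
#' @param reference Reference sequence (a single string).
#' @param rep A [variant_rep]; positions must lie within the reference and
#'   deletion symbol annotations, when present, must match the reference.
#' @return The observed sequence as a single string.
#' @examples
#' patch("CATATATCG", parse_variant("[7delT;8_9insA]", 9))
#' @export
patch <- function(reference, rep) {
  reference <- check_sequence(reference, "reference")
  stopifnot(is_variant_rep(rep))
  n <- nchar(reference)
  if (nrow(rep) == 0L) return(reference)
  del <- rep$op == "del"
  if (any(rep$pos[del] < 1L) || any(rep$pos[del] > n)) {
    abort_varalg("deletion position out of range.", "varalg_range_error")
  }
  if (any(rep$pos[!del] > n)) {
    abort_varalg("insertion anchor out of range.", "varalg_range_error")
  }
  if (anyDuplicated(rep$pos[del])) {
    abort_varalg("duplicate deletion position.", "varalg_patch_error")
  }
  refc <- strsplit(reference, "")[[1]]
  ann <- !is.na(rep$symbol[del])
  if (any(ann) && !all(rep$symbol[del][ann] == refc[rep$pos[del][ann]])) {
    bad <- which(ann & rep$symbol[del] != refc[rep$pos[del]])[1]
    abort_varalg(
      sprintf("deletion annotation mismatch at position %d (reference has %s)",
              rep$pos[del][bad], refc[rep$pos[del][bad]]),
      "varalg_patch_error"
    )
  }
  keep <- rep(TRUE, n)
  keep[rep$pos[del]] <- FALSE
  # Interleave kept reference symbols with insertions: reference position p
  # sorts at 2p, an insertion anchored at p sorts just after, at 2p + 1
  # (ties among insertions keep row order).
  kp <- which(keep)
  tok <- c(refc[kp], rep$symbol[!del])
  key <- c(2L * kp, 2L * rep$pos[!del] + 1L)
  paste(tok[order(key, method = "radix")], collapse = "")
}

#' @export
print.variant_rep <- function(x, ...) {
  desc <- format_variant(x)
  cat(sprintf("<variant representation: %d operation%s>%s\n",
              nrow(x), if (nrow(x) == 1L) "" else "s",
              if (nzchar(desc)) paste0(" ", desc) else ""))
  NextMethod()
}
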