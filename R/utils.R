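# Internal helpers: error conditions, sequence checks, element identities.

abort_varalg <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "varalg_error"), ...)
}

#' @keywords internal
check_sequence <- function(x, arg = "sequence", allow_empty = TRUE) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort_varalg(sprintf("`%s` must be a single string.", arg), "varalg_type_error")
  }
  x <- toupper(gsub("[[:space:]]", "", x))
  if (!allow_empty && !nzchar(x)) {
    abort_varalg(sprintf("`%s` must be non-empty.", arg), "varalg_type_error")
  }
  bad <- unique(strsplit(gsub("[A-Z*]", "", x), "")[[1]])
  if (length(bad) > 0L) {
    abort_varalg(
      sprintf("`%s` contains non-alphabet symbols: %s", arg,
              paste(dQuote(bad, FALSE), collapse = ", ")),
      "varalg_alphabet_error"
    )
  }
  x
}

# Multiset of element identities for a representation: deletions are keyed by
# reference position, insertions by (anchor, symbol).
rep_element_keys <- function(rep) {
  if (nrow(rep) == 0L) return(character())
  ifelse(rep$op == "del",
         paste0("d", rep$pos),
         paste0("i", rep$pos, ":", rep$symbol))
}

# Structural view of a representation used by the sub-representation test:
# deletions as a position set, insertions as per-anchor symbol strings in
# row order.
rep_structure <- function(rep) {
  del <- rep$op == "del"
  list(
    size = nrow(rep),
    dels = rep$pos[del],
    ins = split(rep$symbol[!del], rep$pos[!del])
  )
}

is_subsequence <- function(s, b) {
  if (length(s) == 0L) return(TRUE)
  at <- 0L
  for (ch in s) {
    hit <- which(b == ch & seq_along(b) > at)
    if (length(hit) == 0L) return(FALSE)
    at <- hit[1L]
  }
  TRUE
}

# Is `small` a proper sub-representation of `big`? Deletions must be a
# subset; at every anchor the smaller representation's inserted string must
# be a subsequence of the larger's (the order of insertions sharing an
# anchor is part of the representation, so a plain multiset comparison
# would be too lax). `small` and `big` are rep_structure() values.
is_proper_subrep <- function(small, big) {
  if (small$size >= big$size) return(FALSE)
  if (!all(small$dels %in% big$dels)) return(FALSE)
  for (anchor in names(small$ins)) {
    if (!is_subsequence(small$ins[[anchor]], big$ins[[anchor]])) return(FALSE)
  }
  TRUE
}
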