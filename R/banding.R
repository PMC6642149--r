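#' Parse a five-slot Cepaea banding code
#'
#' Shell banding in *Cepaea nemoralis* is recorded in the standard five-slot
#' positional notation: one character per band (band 1 nearest the apex, band 5
#' on the underside), either `"0"` (band absent) or the band's own digit (band
#' present). Runs of adjacent present bands that are fused into a single dark
#' band are wrapped in parentheses, e.g. `"123(45)"` for a five-banded shell
#' whose bands 4 and 5 have merged.
#'
#' @param code character scalar, e.g. `"00300"`, `"12345"`, `"123(45)"`.
#'
#' @return An object of class `banding_pattern`: a list with
#'   `bands_present` (sorted integer vector, subset of 1:5), `fused_runs`
#'   (list of integer vectors, each a parenthesised run), `fusion_count`
#'   (number of adjacent merges, i.e. `sum(lengths(fused_runs) - 1)`) and
#'   `main_type` (see [classify_banding_type()]).
#'
#' @details A digit is only legal in its own slot: the third character (or the
#'   third digit once parentheses are stripped) must be `"0"` or `"3"`. A
#'   parenthesised run must contain at least two present bands and cannot
#'   contain `"0"`. Malformed codes raise an error naming the offending slot.
#'
#' @examples
#' parse_banding_code("00345")      # three-banded, no fusions
#' parse_banding_code("123(45)")    # five-banded, one merge
#' @seealso [classify_banding_type()], [format_banding_code()]
#' @export
parse_banding_code <- function(code) {
  if (!is.character(code) || length(code) != 1L || is.na(code))
    stop("banding code must be a single character string")
  chars <- strsplit(code, "", fixed = TRUE)[[1L]]
  slot <- 0L
  depth <- 0L
  bands <- integer(0)
  fused_runs <- list()
  run <- integer(0)
  for (ch in chars) {
    if (ch == "(") {
      if (depth > 0L)
        stop(sprintf("malformed banding code '%s': nested '(' before slot %d", code, slot + 1L))
      depth <- 1L
      run <- integer(0)
    } else if (ch == ")") {
      if (depth == 0L)
        stop(sprintf("malformed banding code '%s': unmatched ')' after slot %d", code, slot))
      if (length(run) < 2L)
        stop(sprintf("malformed banding code '%s': fusion run ending at slot %d has fewer than two bands",
                     code, slot))
      fused_runs[[length(fused_runs) + 1L]] <- run
      depth <- 0L
    } else if (ch >= "0" && ch <= "9") {
      slot <- slot + 1L
      if (slot > 5L)
        stop(sprintf("malformed banding code '%s': more than five band slots", code))
      if (ch == "0") {
        if (depth > 0L)
          stop(sprintf("malformed banding code '%s': absent band inside fusion run at slot %d",
                       code, slot))
      } else {
        if (as.integer(ch) != slot)
          stop(sprintf("malformed banding code '%s': digit '%s' in slot %d", code, ch, slot))
        bands <- c(bands, slot)
        if (depth > 0L) run <- c(run, slot)
      }
    } else {
      stop(sprintf("malformed banding code '%s': illegal character '%s' at slot %d", code, ch, slot + 1L))
    }
  }
  if (depth > 0L)
    stop(sprintf("malformed banding code '%s': unclosed '('", code))
  if (slot != 5L)
    stop(sprintf("malformed banding code '%s': expected five band slots, found %d", code, slot))
  structure(
    list(bands_present = bands,
         fused_runs = fused_runs,
         fusion_count = sum(vapply(fused_runs, length, 1L) - 1L),
         main_type = classify_banding_type(bands)),
    class = "banding_pattern")
}

#' Classify a banding pattern into the four main types
#'
#' The four main banding morphs are unbanded (no bands), mid-banded (band 3
#' only), three-banded (bands 3, 4, 5) and five-banded (all five). Any other
#' subset is `"other"` and is excluded from four-type analyses.
#'
#' @param bands a `banding_pattern` or an integer vector of present bands.
#' @return character scalar: one of `"unbanded"`, `"midbanded"`,
#'   `"three_banded"`, `"five_banded"`, `"other"`.
#' @export
classify_banding_type <- function(bands) {
  if (inherits(bands, "banding_pattern")) bands <- bands$bands_present
  bands <- sort(unique(as.integer(bands)))
  if (length(bands) && (any(bands < 1L) || any(bands > 5L)))
    stop("bands must be a subset of 1:5")
  key <- paste(bands, collapse = "")
  if (key == "") return("unbanded")
  switch(key,
         "3" = "midbanded",
         "345" = "three_banded",
         "12345" = "five_banded",
         "other")
}

#' Serialise a banding pattern back to its five-slot code
#'
#' Inverse of [parse_banding_code()]: `parse_banding_code(format_banding_code(p))`
#' reproduces `p` for every well-formed pattern.
#'
#' @param pattern a `banding_pattern`.
#' @return character scalar banding code.
#' @export
format_banding_code <- function(pattern) {
  stopifnot(inherits(pattern, "banding_pattern"))
  slots <- ifelse(1:5 %in% pattern$bands_present, as.character(1:5), "0")
  out <- character(0)
  i <- 1L
  while (i <= 5L) {
    run <- Filter(function(r) r[1L] == i, pattern$fused_runs)
    if (length(run)) {
      r <- run[[1L]]
      out <- c(out, "(", as.character(r), ")")
      i <- r[length(r)] + 1L
    } else {
      out <- c(out, slots[i])
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

#' @export
print.banding_pattern <- function(x, ...) {
  cat(sprintf("<banding_pattern> %s: bands {%s}, %d fusion%s, %s\n",
              format_banding_code(x),
              paste(x$bands_present, collapse = ","),
              x$fusion_count, if (x$fusion_count == 1L) "" else "s",
              x$main_type))
  invisible(x)
}
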