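#' Typed dictionary for the baseline tagger
#'
#' Maps surface strings to entity types. Accepts a named character
#' vector (`c("左" = "Pos_SCP", ...)`), a data frame with `surface`
#' and `label` columns, or a lexicon list as from [default_lexicon()].
#' A surface mapping to two different types is a conflict and is
#' rejected at load.
#'
#' @param x Dictionary source, see Details.
#' @return Object of class `typed_dictionary`: a named character
#'   vector surface -> label with the maximal surface length attached.
#' @export
typed_dictionary <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- data.frame(surface = unlist(x, use.names = FALSE),
                    label = rep(names(x), lengths(x)),
                    stringsAsFactors = FALSE)
  }
  if (is.data.frame(x)) {
    map <- setNames(as.character(x$label), as.character(x$surface))
  } else {
    map <- x
  }
  stopifnot(length(map) > 0L, !is.null(names(map)), all(nzchar(names(map))))
  dup <- split(unname(map), names(map))
  bad <- names(dup)[vapply(dup, function(v) length(unique(v)) > 1L,
                           logical(1))]
  if (length(bad)) {
    stop(sprintf("conflicting dictionary entries for: %s",
                 paste(bad, collapse = ", ")))
  }
  map <- map[!duplicated(names(map))]
  unknown <- setdiff(unique(unname(map)), entity_types())
  if (length(unknown)) {
    stop(sprintf("unknown entity types in dictionary: %s",
                 paste(unknown, collapse = ", ")))
  }
  structure(map, max_len = max(nchar(names(map))),
            class = "typed_dictionary")
}

#' Greedy longest-match dictionary tagging
#'
#' Scans the text left to right; at each position the longest
#' dictionary surface starting there is emitted as an entity and the
#' scan advances past it (so a longer covering term beats its own
#' substrings, mirroring the maximize-coverage annotation principle);
#' unmatched characters are skipped. The output never contains
#' overlapping or nested spans.
#'
#' @param text A single string.
#' @param dict A [typed_dictionary()].
#' @return Entity data frame (`id`, `label`, `start`, `end`, `text`).
#' @export
#' @examples
#' d <- typed_dictionary(c("左" = "Pos_SCP", "手" = "Pos_Pri",
#'                         "手小指" = "Pos_Pri", "疼痛" = "State"))
#' longest_match_tag("左手小指疼痛", d)
longest_match_tag <- function(text, dict) {
  stopifnot(inherits(dict, "typed_dictionary"),
            is.character(text), length(text) == 1L)
  n <- nchar(text)
  max_len <- attr(dict, "max_len")
  out <- list(empty_entities())
  pos <- 0L
  next_id <- 0L
  while (pos < n) {
    hit_len <- 0L
    for (len in min(max_len, n - pos):1) {
      cand <- substr0(text, pos, pos + len)
      if (!is.na(dict[cand])) {
        hit_len <- len
        break
      }
    }
    if (hit_len > 0L) {
      surf <- substr0(text, pos, pos + hit_len)
      out[[length(out) + 1L]] <- data.frame(
        id = next_id, label = unname(dict[[surf]]), start = pos,
        end = pos + hit_len, text = surf, stringsAsFactors = FALSE)
      next_id <- next_id + 1L
      pos <- pos + hit_len
    } else {
      pos <- pos + 1L
    }
  }
  ents <- do.call(rbind, out)
  rownames(ents) <- NULL
  ents
}

#' Read a lexicon TSV
#'
#' Two tab-separated columns, `label` then `surface`, no header.
#'
#' @param path File path.
#' @return Named list of surfaces per label, as [default_lexicon()].
#' @export
read_lexicon <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           col.names = c("label", "surface"),
                           stringsAsFactors = FALSE, encoding = "UTF-8",
                           quote = "")
  split(tab$surface, factor(tab$label, levels = unique(tab$label)))
}

#' Write a lexicon TSV
#'
#' @param lexicon Named list of surfaces per label.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_lexicon <- function(lexicon, path) {
  tab <- data.frame(label = rep(names(lexicon), lengths(lexicon)),
                    surface = unlist(lexicon, use.names = FALSE))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
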