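# Couinaud segment vocabulary and scoring configuration.

#' Couinaud segment vocabulary
#'
#' The nine functional liver segment labels used throughout the package.
#' Segment 4 is split into 4a and 4b because posterosuperior membership
#' differs between the sub-segments (4a is conventionally posterosuperior,
#' 4b anterolateral); a plain `"4"` in input data is expanded according to
#' [segment_config()].
#'
#' @return Character vector of the nine segment labels.
#' @export
#' @examples
#' segment_vocabulary()
segment_vocabulary <- function() {
  c("1", "2", "3", "4a", "4b", "5", "6", "7", "8")
}

# Anatomical adjacency of Couinaud segments, used for the Brisbane rule that
# a major hepatectomy removes at least three *contiguous* segments.  This is
# a standard (necessarily approximate) anatomical neighbourhood graph.
segment_adjacency <- function() {
  list(
    "1"  = c("2", "4a", "7", "8"),
    "2"  = c("1", "3", "4a"),
    "3"  = c("2", "4b"),
    "4a" = c("1", "2", "4b", "8"),
    "4b" = c("3", "4a", "5"),
    "5"  = c("4b", "6", "8"),
    "6"  = c("5", "7"),
    "7"  = c("1", "6", "8"),
    "8"  = c("1", "4a", "5", "7")
  )
}

#' Scoring configuration for the four difficulty scores
#'
#' Collects every tunable of the rule engines that the original score
#' descriptions leave open: which segments count as posterosuperior, the
#' per-segment Iwate location weights (the published description gives only
#' the ranges 1--3 for anterolateral and 4--5 for posterosuperior segments),
#' the Hasegawa location points for segment 1 (not covered by the published
#' 7--8 / 5--6 / 2--3--4 tiers), how a plain segment label `"4"` is expanded,
#' how the Halls 2-point resection rule is parsed, and where a Halls score of
#' exactly 2 falls (the published bins "less than 2" and "3 to 5" omit it).
#'
#' @param posterosuperior Character vector of posterosuperior segment labels.
#' @param iwate_weights Named integer vector of Iwate location points per
#'   segment; anterolateral weights must lie in 1--3, posterosuperior in 4--5.
#' @param hasegawa_points Named integer vector of Hasegawa location points
#'   per segment (published tiers: segments 7--8 = 2, 5--6 = 1, 2--3--4 = 0;
#'   segment 1 defaults to 2, treated like the difficult posterosuperior
#'   segments).
#' @param halls_two_point_requires_ps If `TRUE` (default) the Halls 2-point
#'   tier applies only to anatomical resections of one or two segments that
#'   include a posterosuperior segment; if `FALSE` every non-major anatomical
#'   resection of one or two segments earns 2 points.
#' @param halls_low_max Highest Halls score still classed "low"; default 2
#'   closes the published gap between "less than 2" and "3 to 5".
#' @param plain4 Expansion of a bare `"4"` segment label: `"4b"` (default),
#'   `"4a"`, or `"both"`.
#' @return A list of class `segment_config`.
#' @export
#' @examples
#' cfg <- segment_config()
#' cfg$posterosuperior
segment_config <- function(posterosuperior = c("1", "4a", "7", "8"),
                           iwate_weights = c("1" = 4, "2" = 2, "3" = 1,
                                             "4a" = 4, "4b" = 3, "5" = 3,
                                             "6" = 2, "7" = 5, "8" = 5),
                           hasegawa_points = c("1" = 2, "2" = 0, "3" = 0,
                                               "4a" = 0, "4b" = 0, "5" = 1,
                                               "6" = 1, "7" = 2, "8" = 2),
                           halls_two_point_requires_ps = TRUE,
                           halls_low_max = 2,
                           plain4 = c("4b", "4a", "both")) {
  plain4 <- match.arg(plain4)
  vocab <- segment_vocabulary()
  if (!all(posterosuperior %in% vocab)) {
    stop("posterosuperior labels must be drawn from the segment vocabulary",
         call. = FALSE)
  }
  for (nm in c("iwate_weights", "hasegawa_points")) {
    w <- get(nm)
    if (!all(vocab %in% names(w))) {
      stop(sprintf("%s must cover every segment label", nm), call. = FALSE)
    }
  }
  ps <- vocab %in% posterosuperior
  if (!all(iwate_weights[vocab[ps]] >= 4 & iwate_weights[vocab[ps]] <= 5)) {
    stop("Iwate weights for posterosuperior segments must lie in 4-5",
         call. = FALSE)
  }
  if (!all(iwate_weights[vocab[!ps]] >= 1 & iwate_weights[vocab[!ps]] <= 3)) {
    stop("Iwate weights for anterolateral segments must lie in 1-3",
         call. = FALSE)
  }
  structure(
    list(
      posterosuperior = posterosuperior,
      iwate_weights = iwate_weights,
      hasegawa_points = hasegawa_points,
      halls_two_point_requires_ps = halls_two_point_requires_ps,
      halls_low_max = halls_low_max,
      plain4 = plain4
    ),
    class = "segment_config"
  )
}

#' Parse semicolon-separated segment labels
#'
#' Splits `"7;8"`-style cells into character vectors, expands a bare `"4"`
#' per the configuration, and checks every label against the vocabulary.
#'
#' @param x Character vector of semicolon-separated segment strings, or a
#'   list of character vectors (returned unchanged apart from validation).
#' @param config A [segment_config()].
#' @return A list of character vectors, one per element of `x`.
#' @export
#' @examples
#' parse_segments(c("7;8", "4"))
parse_segments <- function(x, config = segment_config()) {
  if (is.list(x)) {
    segs <- x
  } else {
    segs <- strsplit(trimws(as.character(x)), ";", fixed = TRUE)
    segs <- lapply(segs, trimws)
  }
  expand4 <- switch(config$plain4, "4b" = "4b", "4a" = "4a",
                    both = c("4a", "4b"))
  segs <- lapply(segs, function(s) {
    s <- unlist(lapply(s, function(lab) if (lab == "4") expand4 else lab),
                use.names = FALSE)
    unique(s)
  })
  bad <- vapply(segs, function(s) {
    length(s) == 0 || any(!s %in% segment_vocabulary())
  }, logical(1))
  if (any(bad)) {
    labs <- unique(unlist(segs[bad]))
    labs <- labs[!labs %in% segment_vocabulary()]
    stop(sprintf(
      "invalid or empty segment set%s",
      if (length(labs)) paste0(": label(s) ", paste(labs, collapse = ", "),
                               " not in vocabulary") else ""
    ), call. = FALSE)
  }
  segs
}

# TRUE if the segment set is connected in the adjacency graph.
segments_contiguous <- function(segments) {
  segments <- unique(segments)
  if (length(segments) <= 1) return(TRUE)
  adj <- segment_adjacency()
  seen <- segments[1]
  frontier <- segments[1]
  while (length(frontier) > 0) {
    nbrs <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- setdiff(intersect(nbrs, segments), seen)
    seen <- c(seen, frontier)
  }
  length(seen) == length(segments)
}

# Vectorised over a list of segment sets.
any_posterosuperior <- function(segments, config = segment_config()) {
  vapply(segments, function(s) any(s %in% config$posterosuperior), logical(1))
}
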