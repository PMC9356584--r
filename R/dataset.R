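#' Build a dataset manifest
#'
#' The manifest is the tabular ledger of a dataset: one row per frame (or
#' tile) with its source video, per-class box counts and a background flag.
#' It is the input to splitting, class-distribution reporting and the
#' background-fraction check.
#'
#' @param frames List of [labeled_frame()] or `wild_tile` objects.
#' @param class_names Ordered class names; count columns are
#'   `n_<class>`.
#' @return Tibble with columns `frame_id`, `source_id`, `is_background`,
#'   one `n_<class>` column per class, and `split` (`NA` until assigned).
#' @export
build_manifest <- function(frames, class_names = wildedge_classes()) {
  rows <- purrr::map_dfr(seq_along(frames), function(i) {
    f <- frames[[i]]
    if (inherits(f, "wild_tile")) {
      id <- sprintf("%s_t%02d", f$parent_id, i)
      src <- f$source_id
      boxes <- f$boxes
    } else {
      id <- f$frame_id; src <- f$source_id; boxes <- f$boxes
    }
    counts <- tabulate(boxes$class_id + 1L, nbins = length(class_names))
    out <- tibble(frame_id = id, source_id = src,
                  is_background = nrow(boxes) == 0)
    out[paste0("n_", class_names)] <- as.list(counts)
    out
  })
  if (anyDuplicated(rows$frame_id)) abort("build_manifest: duplicate frame_id")
  rows$split <- NA_character_
  rows
}

count_cols <- function(manifest) grep("^n_", names(manifest), value = TRUE)

#' Split a manifest by source video
#'
#' Assigns every frame of a source video to the same side of the
#' train/validation split, so near-identical consecutive frames can never
#' leak across the boundary and inflate validation scores. Sources are
#' shuffled under `seed` and assigned greedily to the training side until
#' the training frame count first reaches `train_fraction` of the total;
#' the rest go to validation. With whole-video assignment the achieved
#' fraction is as close to the target as the video sizes allow.
#'
#' @param manifest A manifest tibble (see [build_manifest()]).
#' @param train_fraction Target fraction of frames in train (default 0.8,
#'   i.e. an 80:20 split).
#' @param seed Integer seed controlling the shuffle.
#' @return The manifest with the `split` column filled with
#'   `"train"`/`"val"`.
#' @export
split_by_source <- function(manifest, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be in (0, 1)")
  }
  sources <- unique(manifest$source_id)
  if (length(sources) < 2) {
    abort("split_by_source: need >= 2 source videos to split without leakage")
  }
  frames_per_source <- table(manifest$source_id)
  total <- nrow(manifest)
  shuffled <- withr::with_seed(seed, sample(sources))
  cum <- cumsum(as.numeric(frames_per_source[shuffled]))
  n_train_sources <- which(cum >= train_fraction * total)[1]
  train_sources <- shuffled[seq_len(n_train_sources)]
  manifest$split <- ifelse(manifest$source_id %in% train_sources, "train", "val")
  if (all(manifest$split == "train")) {
    # greedy overshoot consumed everything; keep the last source for val
    manifest$split[manifest$source_id == train_sources[n_train_sources]] <- "val"
  }
  manifest
}

#' Per-class frame and box counts by split
#'
#' @param manifest A manifest tibble, optionally with `split` assigned.
#' @return Long tibble: `split`, `class`, `frames` (frames containing at
#'   least one box of the class) and `boxes`.
#' @export
class_distribution <- function(manifest) {
  cols <- count_cols(manifest)
  m <- manifest
  m$split <- ifelse(is.na(m$split), "all", m$split)
  long <- tidyr::pivot_longer(m[c("split", cols)], cols = dplyr::all_of(cols),
                              names_to = "class", values_to = "n")
  long$class <- sub("^n_", "", long$class)
  long$class <- factor(long$class, levels = sub("^n_", "", cols))
  dplyr::summarise(dplyr::group_by(long, .data$split, .data$class),
                   frames = sum(.data$n > 0), boxes = sum(.data$n),
                   .groups = "drop")
}

#' Check the background-image fraction
#'
#' Training sets should contain at least a minimum share of background
#' (object-free) frames to suppress false positives; the working guideline
#' is at least 10%.
#'
#' @param manifest A manifest tibble.
#' @param min_fraction Minimum acceptable background fraction.
#' @return One-row tibble: `n_frames`, `n_background`, `fraction`, `pass`.
#' @export
background_check <- function(manifest, min_fraction = 0.10) {
  if (nrow(manifest) == 0) abort("background_check: empty manifest")
  frac <- mean(manifest$is_background)
  tibble(n_frames = nrow(manifest), n_background = sum(manifest$is_background),
         fraction = frac, pass = frac >= min_fraction)
}

#' Plot the class distribution of a manifest
#'
#' @param manifest A manifest tibble.
#' @param what `"boxes"` or `"frames"`.
#' @return A ggplot.
#' @export
plot_class_distribution <- function(manifest, what = c("boxes", "frames")) {
  what <- match.arg(what)
  d <- class_distribution(manifest)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data[[what]],
                                  fill = .data$split)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = what, fill = "split") +
    ggplot2::theme_minimal()
}
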