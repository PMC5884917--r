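#' Protocol parameters for a precision-stepping session
#'
#' Bundles the geometry and composition of the step-target protocol: targets
#' are spaced one preferred step length apart in the walking (anteroposterior,
#' AP) direction and 20 cm center-to-center mediolaterally (ML), scaled to the
#' shoe, and projected 2 m ahead of the walker on a belt moving at 3 km/h.
#' Perturbed blocks contain unexpected target shifts of 40% of the preferred
#' step length, triggered when the target is at a given available response
#' distance (ARD) from the walker's center of pressure. Forward shifts occur
#' at ARDs of 80, 100, 130 and 200% of the step length; backward shifts only
#' at 130% (catch trials, excluded from analysis).
#'
#' @param preferred_step_length preferred step length L in meters (> 0).
#' @param shoe_length,shoe_width target (shoe) size in meters.
#' @param ml_center_distance mediolateral center-to-center target distance (m).
#' @param belt_speed treadmill belt speed (m/s); default 3 km/h.
#' @param appearance_distance distance ahead of the walker at which targets
#'   appear (m).
#' @param unperturbed_block_size number of targets in the unperturbed block.
#' @param perturbed_block_size number of targets in each perturbed block.
#' @param shifts_per_type repetitions of each shift type per perturbed block
#'   (must be even: half per foot).
#' @param ard_conditions forward-shift ARDs as fractions of L.
#' @param backward_ard ARD (fraction of L) at which backward shifts occur.
#' @param shift_magnitude shift size as a fraction of L, in (0, 1).
#' @param gap_range integer vector `c(min, max)`: number of non-shifted
#'   targets between consecutive shifts.
#' @param n_perturbed_blocks number of perturbed blocks per session.
#' @param first_foot foot of the first target, `"right"` or `"left"`.
#' @return an object of class `protocol_params` (a named list).
#' @export
#' @examples
#' p <- protocol_params(preferred_step_length = 0.5)
#' p$perturbed_block_size
protocol_params <- function(preferred_step_length = 0.5,
                            shoe_length = 0.26,
                            shoe_width = 0.10,
                            ml_center_distance = 0.20,
                            belt_speed = 3 / 3.6,
                            appearance_distance = 2.0,
                            unperturbed_block_size = 59L,
                            perturbed_block_size = 248L,
                            shifts_per_type = 8L,
                            ard_conditions = c(0.8, 1.0, 1.3, 2.0),
                            backward_ard = 1.3,
                            shift_magnitude = 0.4,
                            gap_range = c(5L, 7L),
                            n_perturbed_blocks = 3L,
                            first_foot = c("right", "left")) {
  first_foot <- match.arg(first_foot)
  p <- list(
    preferred_step_length = preferred_step_length,
    shoe_length = shoe_length, shoe_width = shoe_width,
    ml_center_distance = ml_center_distance,
    belt_speed = belt_speed,
    appearance_distance = appearance_distance,
    unperturbed_block_size = as.integer(unperturbed_block_size),
    perturbed_block_size = as.integer(perturbed_block_size),
    shifts_per_type = as.integer(shifts_per_type),
    ard_conditions = sort(ard_conditions),
    backward_ard = backward_ard,
    shift_magnitude = shift_magnitude,
    gap_range = as.integer(gap_range),
    n_perturbed_blocks = as.integer(n_perturbed_blocks),
    first_foot = first_foot
  )
  class(p) <- "protocol_params"
  validate_protocol_params(p)
  p
}

validate_protocol_params <- function(p) {
  if (!is_number(p$preferred_step_length) || p$preferred_step_length <= 0) {
    stopf("preferred_step_length must be a positive number")
  }
  for (f in c("shoe_length", "shoe_width", "ml_center_distance",
              "belt_speed", "appearance_distance")) {
    if (!is_number(p[[f]]) || p[[f]] <= 0) stopf("%s must be positive", f)
  }
  if (length(p$gap_range) != 2 || p$gap_range[1] < 1 ||
      p$gap_range[1] > p$gap_range[2]) {
    stopf("gap_range must be c(min, max) with 1 <= min <= max")
  }
  if (!is_number(p$shift_magnitude) ||
      p$shift_magnitude <= 0 || p$shift_magnitude >= 1) {
    stopf("shift_magnitude must lie in (0, 1)")
  }
  if (!is_count(p$shifts_per_type) || p$shifts_per_type < 2 ||
      p$shifts_per_type %% 2 != 0) {
    stopf("shifts_per_type must be a positive even count (half per foot)")
  }
  if (any(p$ard_conditions <= 0)) stopf("ard_conditions must be positive")
  n_shift <- n_shifts(p)
  if (p$perturbed_block_size < n_shift * (1 + p$gap_range[1])) {
    stopf(paste0(
      "perturbed_block_size (%d) must be at least shifts x (1 + gap_min) ",
      "= %d x %d = %d"
    ), p$perturbed_block_size, n_shift, 1 + p$gap_range[1],
    n_shift * (1 + p$gap_range[1]))
  }
  invisible(p)
}

# number of shifted targets per perturbed block: forward ARDs + one backward
n_shifts <- function(p) p$shifts_per_type * (length(p$ard_conditions) + 1L)

shift_types <- function(p) {
  data.frame(
    direction = c(rep("forward", length(p$ard_conditions)), "backward"),
    ard = c(p$ard_conditions, p$backward_ard),
    stringsAsFactors = FALSE
  )
}

foot_sequence <- function(n, first_foot) {
  feet <- c("right", "left")
  if (first_foot == "left") feet <- rev(feet)
  rep_len(feet, n)
}

# signed ML target center: positive toward the walker's right
ml_center_for <- function(foot, p) {
  ifelse(foot == "right", 1, -1) * p$ml_center_distance / 2
}

new_block <- function(p, n, kind) {
  foot <- foot_sequence(n, p$first_foot)
  b <- data.frame(
    index = seq_len(n),
    foot = foot,
    nominal_ap_center = (seq_len(n) - 1) * p$preferred_step_length,
    ml_center = ml_center_for(foot, p),
    size_length = p$shoe_length,
    size_width = p$shoe_width,
    shift_direction = NA_character_,
    shift_ard = NA_real_,
    displaced_ap_center = NA_real_,
    stringsAsFactors = FALSE
  )
  attr(b, "kind") <- kind
  attr(b, "params") <- p
  class(b) <- c("step_block", "data.frame")
  b
}

#' Generate an unperturbed block of step targets
#'
#' A series of non-shifting targets with alternating feet, AP spacing equal
#' to the preferred step length and ML spacing `ml_center_distance`.
#'
#' @param params a [protocol_params()] object.
#' @return a `step_block` data frame (one row per target) with attribute
#'   `kind = "unperturbed"`.
#' @export
#' @examples
#' b <- generate_unperturbed_block(protocol_params())
#' nrow(b)  # 59
generate_unperturbed_block <- function(params) {
  validate_protocol_params(params)
  new_block(params, params$unperturbed_block_size, "unperturbed")
}

#' Generate a perturbed block of step targets
#'
#' Builds a block in which each shift type (one per forward ARD plus the
#' backward catch type) is repeated `shifts_per_type` times, balanced across
#' feet, with consecutive shifts separated by `gap_range[1]` to
#' `gap_range[2]` non-shifted targets. Gaps are sampled uniformly on the gap
#' range and then randomly decremented toward the minimum until the shifts
#' and gaps fit the block; the gap vector is resampled until the shift slots
#' split evenly across the two feet.
#'
#' @param params a [protocol_params()] object.
#' @param seed integer seed controlling gap sampling and type assignment.
#' @return a `step_block` with attribute `kind = "perturbed"`.
#' @export
#' @examples
#' b <- generate_perturbed_block(protocol_params(), seed = 1)
#' sum(!is.na(b$shift_direction))  # 40
generate_perturbed_block <- function(params, seed) {
  validate_protocol_params(params)
  p <- params
  n <- p$perturbed_block_size
  k <- n_shifts(p)
  fillers <- n - k
  gmin <- p$gap_range[1]
  gmax <- p$gap_range[2]
  lead <- gmin
  if (fillers < lead + (k - 1) * gmin) {
    stopf("block of %d targets cannot hold %d shifts with gaps >= %d (needs >= %d targets)",
          n, k, gmin, k + lead + (k - 1) * gmin)
  }

  with_seed(seed, {
    slots <- NULL
    for (attempt in seq_len(10000L)) {
      gaps <- sample(seq.int(gmin, gmax), k - 1, replace = TRUE)
      excess <- lead + sum(gaps) - fillers
      while (excess > 0) {
        idx <- which(gaps > gmin)
        take <- sample(idx, min(excess, length(idx)))
        gaps[take] <- gaps[take] - 1L
        excess <- lead + sum(gaps) - fillers
      }
      pos <- cumsum(c(lead + 1L, gaps + 1L))
      if (sum(pos %% 2 == 1) == k / 2) {
        slots <- pos
        break
      }
    }
    if (is.null(slots)) {
      stopf("could not balance shift slots across feet for this design")
    }

    types <- shift_types(p)
    half <- p$shifts_per_type / 2
    odd <- sample(slots[slots %% 2 == 1])
    even <- sample(slots[slots %% 2 == 0])
    assign_idx <- c(odd, even)
    assign_type <- c(rep(seq_len(nrow(types)), each = half),
                     rep(seq_len(nrow(types)), each = half))

    b <- new_block(p, n, "perturbed")
    L <- p$preferred_step_length
    for (j in seq_along(assign_idx)) {
      i <- assign_idx[j]
      ty <- types[assign_type[j], ]
      b$shift_direction[i] <- ty$direction
      b$shift_ard[i] <- ty$ard
      sgn <- if (ty$direction == "forward") 1 else -1
      b$displaced_ap_center[i] <-
        b$nominal_ap_center[i] + sgn * p$shift_magnitude * L
    }
    b
  })
}

#' Generate a full session of blocks
#'
#' One unperturbed block plus `n_perturbed_blocks` perturbed blocks, in a
#' seeded random presentation order.
#'
#' @param params a [protocol_params()] object.
#' @param seed integer seed.
#' @return a list of `step_block`s of class `step_session`.
#' @export
generate_session <- function(params, seed) {
  validate_protocol_params(params)
  nb <- params$n_perturbed_blocks + 1L
  seeds <- derive_seeds(seed, nb + 1L)
  blocks <- c(
    list(generate_unperturbed_block(params)),
    lapply(seq_len(params$n_perturbed_blocks), function(i) {
      generate_perturbed_block(params, seed = seeds[i])
    })
  )
  ord <- with_seed(seeds[nb + 1L], sample.int(nb))
  blocks <- blocks[ord]
  class(blocks) <- "step_session"
  attr(blocks, "params") <- params
  blocks
}

#' Lab-frame position of a target at a given time
#'
#' Targets are fixed to the belt: they appear `appearance_distance` ahead of
#' the walker and approach at the belt speed. The lab frame has its origin at
#' the walker, AP positive in the walking direction.
#'
#' @param target a one-row `step_block` slice (or list with `ml_center`).
#' @param t time (s) at which to evaluate; must be `>= appearance_time`.
#' @param appearance_time time (s) at which the target appeared.
#' @param params a [protocol_params()] object.
#' @return named numeric `c(ap = , ml = )` in meters.
#' @export
target_lab_position <- function(target, t, appearance_time, params) {
  if (any(t < appearance_time)) {
    stopf("target position requested at t = %g before its appearance at %g",
          min(t), appearance_time)
  }
  c(ap = params$appearance_distance - params$belt_speed * (t - appearance_time),
    ml = as.numeric(target$ml_center))
}

#' @export
print.step_block <- function(x, ...) {
  k <- sum(!is.na(x$shift_direction))
  cat(sprintf("<step_block: %s, %d targets, %d shifted>\n",
              attr(x, "kind"), nrow(x), k))
  invisible(x)
}

#' @export
print.step_session <- function(x, ...) {
  kinds <- vapply(x, function(b) attr(b, "kind"), character(1))
  cat(sprintf("<step_session: %d blocks (%s)>\n",
              length(x), paste(kinds, collapse = ", ")))
  invisible(x)
}

#' Serialize a protocol session or block to JSON
#'
#' @param x a `step_block` or `step_session`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_protocol_json <- function(x, path) {
  as_blk <- function(b) {
    list(kind = attr(b, "kind"),
         params = unclass(attr(b, "params")),
         targets = b)
  }
  obj <- if (inherits(x, "step_session")) {
    list(session = lapply(unclass(x), as_blk))
  } else {
    as_blk(x)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Read a protocol block or session written by [write_protocol_json()]
#' @param path JSON file path.
#' @return a `step_block` or `step_session`.
#' @export
read_protocol_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  from_blk <- function(blk) {
    p <- lapply(blk$params, function(x) {
      if (is.list(x)) unlist(x) else x
    })
    p$gap_range <- as.integer(p$gap_range)
    class(p) <- "protocol_params"
    b <- do.call(rbind, lapply(blk$targets, function(row) {
      row <- lapply(row, function(x) if (is.null(x)) NA else x)
      as.data.frame(row, stringsAsFactors = FALSE)
    }))
    for (col in c("shift_direction")) {
      if (!col %in% names(b)) b[[col]] <- NA_character_
    }
    for (col in c("shift_ard", "displaced_ap_center")) {
      if (!col %in% names(b)) b[[col]] <- NA_real_
      b[[col]] <- as.numeric(b[[col]])
    }
    b$shift_direction <- as.character(b$shift_direction)
    attr(b, "kind") <- blk$kind
    attr(b, "params") <- p
    class(b) <- c("step_block", "data.frame")
    b
  }
  if (!is.null(obj$session)) {
    out <- lapply(obj$session, from_blk)
    class(out) <- "step_session"
    attr(out, "params") <- attr(out[[1]], "params")
    out
  } else {
    from_blk(obj)
  }
}
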