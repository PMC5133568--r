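#' Construct a lineage tree
#'
#' A `lineage_tree` holds one digital embryo: one record per (cell, time
#' step), the division structure implied by `mother_id`, and the observation
#' window. Times are minutes; positions micrometres; volumes um^3; surfaces
#' um^2. `type` is one of [CELL_TYPES] (or `NA` before label propagation),
#' `gen` the generation rank (`NA` before [assign_generations_and_types()]).
#'
#' @param records A data frame with columns `cell_id`, `mother_id`, `t`,
#'   `x`, `y`, `z`, `type`, `volume`, `surface` and optionally `gen`,
#'   `degree`.
#' @param window Numeric length-2 observation window `(t_start, t_end)`;
#'   defaults to the range of `records$t`.
#' @param validate Run [validate_lineage()] on the result.
#' @return An object of class `lineage_tree`.
#' @export
lineage_tree <- function(records, window = NULL, validate = FALSE) {
  need <- c("cell_id", "mother_id", "t", "x", "y", "z", "type", "volume", "surface")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  rec <- as.data.frame(records, stringsAsFactors = FALSE)
  rec$cell_id <- as.integer(rec$cell_id)
  rec$mother_id <- as.integer(rec$mother_id)
  for (cl in c("t", "x", "y", "z", "volume", "surface")) rec[[cl]] <- as.numeric(rec[[cl]])
  rec$type <- as.character(rec$type)
  if (is.null(rec$gen)) rec$gen <- NA_integer_
  rec <- rec[order(rec$cell_id, rec$t), , drop = FALSE]
  rownames(rec) <- NULL
  if (is.null(window)) window <- range(rec$t)
  tree <- structure(list(records = rec, window = as.numeric(window)),
                    class = "lineage_tree")
  if (validate) validate_lineage(tree)
  tree
}

#' @export
print.lineage_tree <- function(x, ...) {
  rec <- x$records
  cat(sprintf(
    "<lineage_tree: %d cells, %d records, window [%.1f, %.1f] min>\n",
    length(unique(rec$cell_id)), nrow(rec), x$window[1], x$window[2]
  ))
  invisible(x)
}

# one row per cell: id, mother, first/last observed time, type, gen
cell_index <- function(tree) {
  rec <- tree$records
  dt <- data.table::as.data.table(rec)
  t <- NULL # appease R CMD check
  idx <- dt[, list(
    mother_id = mother_id[1L], first_t = min(t), last_t = max(t),
    n_steps = .N, type = type[1L], gen = gen[1L],
    vbar = mean(volume), sbar = mean(surface)
  ), by = "cell_id"]
  as.data.frame(idx)
}

# map cell_id -> integer vector of daughter ids
division_map <- function(tree) {
  idx <- cell_index(tree)
  d <- idx[!is.na(idx$mother_id), c("mother_id", "cell_id")]
  split(d$cell_id, d$mother_id)
}

#' Validate a lineage tree
#'
#' Checks the structural invariants of a digital lineage: strictly positive
#' volumes/surfaces where present, every cell with 0 or exactly 2 daughters,
#' contiguous per-cell tracks on the acquisition time grid, daughters
#' starting at the time step immediately after the mother's last one,
#' mothers missing only for cells present at the first observed time step,
#' and all mother references resolving.
#'
#' @param tree A [lineage_tree()].
#' @return `tree`, invisibly. Errors name the offending cells.
#' @export
validate_lineage <- function(tree) {
  rec <- tree$records
  if (nrow(rec) == 0L) stop("lineage has no records")
  if (any(rec$t < 0)) stop("negative times in records")
  if (any(!is.na(rec$volume) & rec$volume <= 0)) {
    stop("non-positive volume for cell(s): ",
         paste(unique(rec$cell_id[!is.na(rec$volume) & rec$volume <= 0]), collapse = ", "))
  }
  if (any(!is.na(rec$surface) & rec$surface <= 0)) {
    stop("non-positive surface for cell(s): ",
         paste(unique(rec$cell_id[!is.na(rec$surface) & rec$surface <= 0]), collapse = ", "))
  }
  if (anyDuplicated(rec[, c("cell_id", "t")])) stop("duplicated (cell_id, t) records")

  idx <- cell_index(tree)
  ids <- idx$cell_id

  # mother references resolve
  mo <- idx$mother_id
  bad <- !is.na(mo) & !(mo %in% ids)
  if (any(bad)) {
    stop("missing mother reference for cell(s): ",
         paste(idx$cell_id[bad], collapse = ", "))
  }

  # 0 or exactly 2 daughters
  ndaught <- table(mo[!is.na(mo)])
  wrong <- names(ndaught)[ndaught != 2L]
  if (length(wrong)) {
    stop("cell(s) with a number of daughters other than 2: ",
         paste(wrong, collapse = ", "))
  }

  # contiguity on the global time grid
  grid <- sort(unique(rec$t))
  pos <- match(rec$t, grid)
  cont <- tapply(pos, rec$cell_id, function(p) all(diff(sort(p)) == 1L))
  if (!all(cont)) {
    stop("non-contiguous track for cell(s): ",
         paste(names(cont)[!cont], collapse = ", "))
  }

  # daughters start strictly after (and immediately after) mother's last step
  has_mo <- !is.na(mo)
  if (any(has_mo)) {
    m_last <- idx$last_t[match(mo[has_mo], ids)]
    d_first <- idx$first_t[has_mo]
    if (any(d_first <= m_last)) {
      stop("daughter track starting no later than mother's last step: cell(s) ",
           paste(idx$cell_id[has_mo][d_first <= m_last], collapse = ", "))
    }
    gap <- match(d_first, grid) - match(m_last, grid)
    if (any(gap != 1L)) {
      stop("daughter not starting at the step after mother's last: cell(s) ",
           paste(idx$cell_id[has_mo][gap != 1L], collapse = ", "))
    }
  }

  # roots only at the first observed time step
  t0 <- grid[1L]
  orphan <- is.na(mo) & idx$first_t > t0
  if (any(orphan)) {
    stop("cell(s) without mother appearing after the first time step: ",
         paste(idx$cell_id[orphan], collapse = ", "))
  }
  invisible(tree)
}

#' Propagate generation ranks and type labels from the roots
#'
#' Root cells (those without a mother) receive `root_generation` and their
#' label from `root_labels` (or keep their pre-existing label); both are then
#' propagated along the filiation: generation increases by one per division
#' and the type is inherited unchanged.
#'
#' @param tree A [lineage_tree()].
#' @param root_generation Generation rank of the root cells. The 32-cell
#'   stage is generation 6.
#' @param root_labels Optional named vector (names = root cell ids) of type
#'   labels among [CELL_TYPES].
#' @return The tree with `gen` and `type` filled on every record.
#' @export
assign_generations_and_types <- function(tree, root_generation = 6L,
                                         root_labels = NULL) {
  idx <- cell_index(tree)
  ids <- idx$cell_id
  roots <- ids[is.na(idx$mother_id)]
  lab <- idx$type[match(roots, ids)]
  names(lab) <- roots
  if (!is.null(root_labels)) {
    lab[names(root_labels)] <- unname(root_labels)
  }
  unl <- roots[is.na(lab[as.character(roots)]) | !lab[as.character(roots)] %in% CELL_TYPES]
  if (length(unl)) {
    stop("unlabelled root cell(s): ", paste(unl, collapse = ", "))
  }

  gen <- rep(NA_integer_, length(ids)); names(gen) <- ids
  typ <- rep(NA_character_, length(ids)); names(typ) <- ids
  gen[as.character(roots)] <- as.integer(root_generation)
  typ[as.character(roots)] <- lab[as.character(roots)]

  mo <- idx$mother_id
  # breadth-first: order cells by first observed time, mothers come first
  ord <- order(idx$first_t)
  for (i in ord) {
    if (!is.na(mo[i])) {
      key <- as.character(ids[i]); mkey <- as.character(mo[i])
      gen[key] <- gen[mkey] + 1L
      typ[key] <- typ[mkey]
    }
  }
  rec <- tree$records
  pos <- match(as.character(rec$cell_id), names(gen))
  rec$gen <- unname(gen[pos])
  rec$type <- unname(typ[pos])
  tree$records <- rec
  tree
}
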