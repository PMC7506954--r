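#' The 19 carried-load conditions of the carrying-gait protocol
#'
#' Enumerates the full trial protocol: one unloaded control walk, three
#' 30-lb box carries (symmetric, left-heavy, right-heavy), and all fifteen
#' dumbbell combinations with 0, 5, 15 or 25 lb per hand (excluding the
#' empty-handed combination, which is the control condition).
#'
#' The order is canonical and stable: control first, then the three box
#' conditions (symmetric, left-heavy, right-heavy), then the dumbbell
#' conditions sorted lexicographically by `(left_lb, right_lb)`.
#' Per-participant trial-order randomization is the job of the cohort
#' generator, not of this table.
#'
#' @return A data.frame with 19 rows and columns `condition_id` (unique
#'   string key), `carry_mode` (`"none"`, `"box"` or `"dumbbells"`),
#'   `left_lb` and `right_lb` (weight carried on each side, pounds).
#' @examples
#' cond <- load_conditions()
#' table(cond$carry_mode)
#' @export
load_conditions <- function() {
  box <- data.frame(
    condition_id = c("box_15_15", "box_25_5", "box_5_25"),
    carry_mode = "box",
    left_lb = c(15, 25, 5),
    right_lb = c(15, 5, 25)
  )
  weights <- c(0, 5, 15, 25)
  db <- expand.grid(right_lb = weights, left_lb = weights)[, c("left_lb", "right_lb")]
  db <- db[order(db$left_lb, db$right_lb), ]
  db <- db[db$left_lb + db$right_lb > 0, ]
  db <- data.frame(
    condition_id = sprintf("db_%d_%d", db$left_lb, db$right_lb),
    carry_mode = "dumbbells",
    left_lb = db$left_lb,
    right_lb = db$right_lb
  )
  out <- rbind(
    data.frame(condition_id = "none", carry_mode = "none", left_lb = 0, right_lb = 0),
    box, db
  )
  rownames(out) <- NULL
  stopifnot(nrow(out) == 19, !anyDuplicated(out$condition_id))
  out
}

#' Absolute left/right load asymmetry of a condition, in pounds
#'
#' @param conditions A data.frame with `left_lb` and `right_lb` columns
#'   (one or more rows of [load_conditions()]).
#' @return Numeric vector, `abs(left_lb - right_lb)`.
#' @export
condition_asymmetry <- function(conditions) {
  abs(conditions$left_lb - conditions$right_lb)
}

#' The five classification problems
#'
#' Defines the five load classification problems studied by the pipeline:
#' * `P1` — box vs. no box (2 classes, all 19 conditions);
#' * `P2` — box vs. one dumbbell vs. two dumbbells (control and the three
#'   symmetric dumbbell pairs skipped, so each class holds the printed
#'   3/6/6 conditions);
#' * `P3` — symmetric vs. `<20` lb vs. `>=20` lb left/right difference
#'   (box trials skipped; control counts as symmetric);
#' * `P4` — symmetric vs. `<=10` lb vs. `>10` lb difference (box skipped);
#' * `P5` — symmetric vs. heavier-left vs. heavier-right (box skipped).
#'
#' Class labels are ordered; their position is the integer class code used
#' by the regression-rounded classifier (1..K).
#'
#' @return Named list of problem definitions, each a list with
#'   `problem_id`, `classes` (ordered character vector) and `description`.
#' @export
problem_definitions <- function() {
  list(
    P1 = list(
      problem_id = "P1",
      classes = c("box", "no box"),
      description = "frontal box carry vs. any other load (dumbbells or none)"
    ),
    P2 = list(
      problem_id = "P2",
      classes = c("box", "1 dumbbell", "2 dumbbells"),
      description = "load position: box vs. unilateral vs. bilateral side load"
    ),
    P3 = list(
      problem_id = "P3",
      classes = c("symmetric", "<20 lb difference", ">=20 lb difference"),
      description = "load asymmetry with a 20 lb threshold"
    ),
    P4 = list(
      problem_id = "P4",
      classes = c("symmetric", "<=10 lb difference", ">10 lb difference"),
      description = "load asymmetry with a 10 lb threshold"
    ),
    P5 = list(
      problem_id = "P5",
      classes = c("symmetric", "heavier left", "heavier right"),
      description = "which side carries the heavier load"
    )
  )
}

resolve_problem <- function(problem) {
  if (is.character(problem) && length(problem) == 1) {
    defs <- problem_definitions()
    if (!problem %in% names(defs)) {
      stop("unknown problem id: ", problem)
    }
    return(defs[[problem]])
  }
  if (is.list(problem) && all(c("problem_id", "classes") %in% names(problem))) {
    return(problem)
  }
  stop("`problem` must be a problem id (\"P1\"..\"P5\") or a problem definition")
}

#' Map each condition to its class label under a classification problem
#'
#' Conditions that a problem excludes (the control walk for `P2`, the three
#' box carries for `P3`-`P5`) map to `NA` ("skip"). The mapping is total
#' and deterministic over the 19-condition protocol.
#'
#' @param conditions data.frame of conditions as from [load_conditions()].
#' @param problem A problem id (`"P1"`..`"P5"`) or a definition from
#'   [problem_definitions()].
#' @return Character vector of class labels (one per row of `conditions`),
#'   `NA` for skipped conditions.
#' @examples
#' cond <- load_conditions()
#' table(label_condition(cond, "P3"), useNA = "ifany")
#' @export
label_condition <- function(conditions, problem) {
  problem <- resolve_problem(problem)
  known <- load_conditions()$condition_id
  if (!all(conditions$condition_id %in% known)) {
    stop(
      "unknown condition id(s): ",
      paste(setdiff(conditions$condition_id, known), collapse = ", ")
    )
  }
  mode <- conditions$carry_mode
  asym <- condition_asymmetry(conditions)
  cls <- problem$classes
  lab <- switch(problem$problem_id,
    P1 = ifelse(mode == "box", cls[1], cls[2]),
    P2 = ifelse(mode == "none", NA_character_,
      ifelse(mode == "box", cls[1],
        ifelse(pmin(conditions$left_lb, conditions$right_lb) == 0, cls[2],
          ifelse(asym == 0, NA_character_, cls[3])
        )
      )
    ),
    P3 = ifelse(mode == "box", NA_character_,
      ifelse(asym == 0, cls[1], ifelse(asym < 20, cls[2], cls[3]))
    ),
    P4 = ifelse(mode == "box", NA_character_,
      ifelse(asym == 0, cls[1], ifelse(asym <= 10, cls[2], cls[3]))
    ),
    P5 = ifelse(mode == "box", NA_character_,
      ifelse(asym == 0, cls[1],
        ifelse(conditions$left_lb > conditions$right_lb, cls[2], cls[3])
      )
    ),
    stop("unknown problem id: ", problem$problem_id)
  )
  lab
}

#' Integer class codes (1..K) for a problem's labels
#'
#' @param labels Character labels as returned by [label_condition()].
#' @param problem Problem id or definition.
#' @return Integer codes in listing order of the problem's classes; `NA`
#'   propagates.
#' @export
class_codes <- function(labels, problem) {
  problem <- resolve_problem(problem)
  codes <- match(labels, problem$classes)
  if (any(!is.na(labels) & is.na(codes))) {
    stop("labels not in problem ", problem$problem_id, "'s class list")
  }
  as.integer(codes)
}

#' Number of protocol conditions in each class of a problem
#'
#' @param problem Problem id or definition.
#' @return Named integer vector (one entry per class, in class order);
#'   skipped conditions are not counted.
#' @examples
#' class_counts("P2") # 3 box, 6 one-dumbbell, 6 two-dumbbell conditions
#' @export
class_counts <- function(problem) {
  problem <- resolve_problem(problem)
  lab <- label_condition(load_conditions(), problem)
  counts <- vapply(problem$classes, function(cl) sum(lab == cl, na.rm = TRUE), integer(1))
  counts
}

#' Export / import the condition table and problem definitions as JSON
#'
#' A small versioned interchange schema so that the protocol can be shared
#' with non-R tooling: `{"format_version": "1.0", "conditions": [...],
#' "problems": [...]}`.
#'
#' @param path File path to write to / read from.
#' @return `write_protocol_json()` returns `path` invisibly;
#'   `read_protocol_json()` returns `list(conditions = <data.frame>,
#'   problems = <list>)`.
#' @export
write_protocol_json <- function(path) {
  defs <- problem_definitions()
  doc <- list(
    format_version = "1.0",
    conditions = load_conditions(),
    problems = lapply(unname(defs), function(p) {
      list(problem_id = p$problem_id, classes = p$classes, description = p$description)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format_version)) stop("not a protocol JSON document: ", path)
  cond <- as.data.frame(doc$conditions)
  if (nrow(cond) != 19) stop("expected 19 conditions, found ", nrow(cond))
  probs <- doc$problems
  if (is.data.frame(probs)) {
    probs <- lapply(seq_len(nrow(probs)), function(i) {
      list(
        problem_id = probs$problem_id[i],
        classes = probs$classes[[i]],
        description = probs$description[i]
      )
    })
  }
  names(probs) <- vapply(probs, `[[`, character(1), "problem_id")
  list(conditions = cond, problems = probs)
}
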