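#' Generate an order sheet
#'
#' An order sheet holds 1--3 item lists for one picking session. The picking
#' floor has exactly six areas (A--F), each stocked with four item types; a
#' list names up to three areas and for each a requested item and a count of
#' at most three. A `simple` sheet is constructed so that neither areas nor
#' items overlap between its lists; a `complex` sheet forces at least one
#' shared area (and item) between lists.
#'
#' @param complexity_class `"simple"` or `"complex"`
#' @param seed integer seed
#' @return an object of class `order_sheet`: a list with `complexity_class`
#'   and `lists`, each list a data.frame with columns `area`, `item`, `count`
#' @examples
#' sh <- synthesize_order_sheets("simple", seed = 1)
#' sh$complexity_class
#' @export
synthesize_order_sheets <- function(complexity_class = c("simple", "complex"),
                                    seed = 1L) {
  complexity_class <- match.arg(complexity_class)
  areas <- LETTERS[1:6]
  with_seed(derive_seed(seed, 211L), {
    if (complexity_class == "simple") {
      n_lists <- sample(1:3, 1L)
      # disjoint area blocks: at most floor(6 / n_lists) areas per list
      per_list <- min(3L, 6L %/% n_lists)
      pool <- sample(areas)
      lists <- lapply(seq_len(n_lists), function(l) {
        a <- pool[((l - 1L) * per_list + 1L):(l * per_list)]
        data.frame(area = a,
                   item = sample(1:4, length(a), replace = TRUE),
                   count = sample(1:3, length(a), replace = TRUE),
                   stringsAsFactors = FALSE)
      })
    } else {
      n_lists <- sample(2:3, 1L)
      lists <- lapply(seq_len(n_lists), function(l) {
        a <- sample(areas, 3L)
        data.frame(area = a,
                   item = sample(1:4, 3L, replace = TRUE),
                   count = sample(1:3, 3L, replace = TRUE),
                   stringsAsFactors = FALSE)
      })
      # force at least one shared (area, item) line between lists 1 and 2
      shared <- lists[[1L]][sample(nrow(lists[[1L]]), 1L), ]
      lists[[2L]][1L, c("area", "item")] <- shared[, c("area", "item")]
    }
    structure(list(complexity_class = complexity_class, lists = lists),
              class = "order_sheet")
  })
}

#' @export
print.order_sheet <- function(x, ...) {
  cat(sprintf("<order_sheet> %s, %d list(s)\n", x$complexity_class, length(x$lists)))
  for (i in seq_along(x$lists)) {
    df <- x$lists[[i]]
    cat(sprintf("  list %d: %s\n", i,
                paste(sprintf("%s#%d x%d", df$area, df$item, df$count), collapse = ", ")))
  }
  invisible(x)
}

sheet_areas <- function(sheet) {
  unique(unlist(lapply(sheet$lists, function(df) df$area)))
}

#' Nine-dimensional task-complexity encoding of an order sheet
#'
#' Encodes an order sheet and its working time as the nine scalar components
#' used alongside every device group's features: six 0/1 area dummies
#' (`l_A`..`l_F`, set when the area appears in any list), the mean and the
#' (population) standard deviation of the per-list area dummies -- the degree
#' of overlap between lists -- and the working time in seconds.
#'
#' @param sheet an [synthesize_order_sheets()] result
#' @param t working time in seconds, in (0, 60\]
#' @return named numeric vector of length 9:
#'   `l_A`..`l_F`, `m(l)`, `sigma(l)`, `t`
#' @examples
#' sh <- synthesize_order_sheets("simple", seed = 2)
#' task_complexity(sh, t = 40)
#' @export
task_complexity <- function(sheet, t) {
  if (!inherits(sheet, "order_sheet")) stop("`sheet` must be an order_sheet", call. = FALSE)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t <= 0 || t > 60) {
    stop("working time `t` must lie in (0, 60]", call. = FALSE)
  }
  areas <- LETTERS[1:6]
  for (df in sheet$lists) {
    if (any(!df$area %in% areas)) {
      stop("unknown area code: ", paste(setdiff(df$area, areas), collapse = ", "),
           call. = FALSE)
    }
  }
  l <- as.numeric(areas %in% sheet_areas(sheet))
  if (length(sheet$lists)) {
    dummies <- vapply(sheet$lists, function(df) as.numeric(areas %in% df$area),
                      numeric(6L))  # 6 x n_lists
    overlap_mean <- mean(dummies)
    overlap_sd <- sd_pop(as.numeric(dummies))
  } else {
    overlap_mean <- 0
    overlap_sd <- 0
  }
  stats::setNames(c(l, overlap_mean, overlap_sd, t),
                  c(paste0("l_", areas), "m(l)", "sigma(l)", "t"))
}

#' Work efficiency of a picking session
#'
#' `w = 1 - t/60`: the fraction of the one-minute session budget left over
#' when the list was completed in `t` seconds.
#'
#' @param t working time in seconds, in (0, 60\]
#' @return efficiency in \[0, 1)
#' @examples
#' work_efficiency(30)  # 0.5
#' @export
work_efficiency <- function(t) {
  if (!is.numeric(t) || any(is.na(t)) || any(t <= 0) || any(t > 60)) {
    stop("working time `t` must lie in (0, 60]", call. = FALSE)
  }
  1 - t / 60
}
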