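#' Centerlines as tibbles
#'
#' A centerline is an ordered polyline of lumen-centre samples in world
#' millimetres, stored as a tibble with columns `x`, `y`, `z` and optionally
#' `r` (local lumen radius, mm). Reference (ground-truth) centerlines carry
#' radii; tracker output usually does not.
#'
#' @param points a data frame with columns `x`, `y`, `z` and optionally `r`,
#'   or an n x 3 / n x 4 numeric matrix.
#' @param label free-text branch label (e.g. "RCA", "LAD", "branch").
#' @return A tibble of class `centerline` with attribute `label`.
#' @examples
#' cl <- centerline(cbind(0, 0, seq(0, 10, by = 0.5), 1.2), label = "toy")
#' centerline_length(cl)
#' @export
centerline <- function(points, label = "") {
  if (is.matrix(points)) {
    stopifnot(ncol(points) %in% c(3L, 4L))
    colnames(points) <- c("x", "y", "z", "r")[seq_len(ncol(points))]
    points <- tibble::as_tibble(points)
  }
  points <- tibble::as_tibble(points)
  if (!all(c("x", "y", "z") %in% names(points))) {
    stop("centerline needs columns x, y, z", call. = FALSE)
  }
  points <- points[, intersect(c("x", "y", "z", "r"), names(points))]
  if (nrow(points) < 2L) {
    stop("a centerline needs at least 2 points", call. = FALSE)
  }
  xyz <- as.matrix(points[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite centerline coordinates", call. = FALSE)
  seg <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-nrow(xyz), , drop = FALSE])^2))
  if (any(seg == 0)) {
    stop("consecutive centerline points must be distinct", call. = FALSE)
  }
  if ("r" %in% names(points) && any(points$r <= 0, na.rm = TRUE)) {
    stop("centerline radii must be positive", call. = FALSE)
  }
  structure(points, class = c("centerline", class(tibble::tibble())),
            label = as.character(label))
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> '%s': %d points, length %.2f mm%s\n",
              attr(x, "label") %||% "", nrow(x), centerline_length(x),
              if ("r" %in% names(x)) sprintf(", radii %.2f-%.2f mm",
                                             min(x$r), max(x$r)) else ""))
  NextMethod()
}

cl_xyz <- function(cl) as.matrix(cl[, c("x", "y", "z")])

#' Total arclength of a centerline (mm)
#' @param cl a [centerline()].
#' @export
centerline_length <- function(cl) {
  xyz <- cl_xyz(cl)
  sum(sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-nrow(xyz), , drop = FALSE])^2)))
}

#' Resample a centerline to uniform arclength spacing
#'
#' Positions (and radii, when present) are linearly interpolated along
#' arclength. The first and last original points are always retained.
#'
#' @param cl a [centerline()].
#' @param spacing target arclength spacing, mm.
#' @return A [centerline()] with points every `spacing` mm.
#' @export
resample_centerline <- function(cl, spacing) {
  stopifnot(spacing > 0)
  xyz <- cl_xyz(cl)
  seg <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-nrow(xyz), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  n_out <- max(2L, ceiling(total / spacing) + 1L)
  si <- seq(0, total, length.out = n_out)
  out <- cbind(
    stats::approx(s, xyz[, 1], xout = si)$y,
    stats::approx(s, xyz[, 2], xout = si)$y,
    stats::approx(s, xyz[, 3], xout = si)$y
  )
  if ("r" %in% names(cl)) {
    out <- cbind(out, stats::approx(s, cl$r, xout = si)$y)
  }
  centerline(out, label = attr(cl, "label") %||% "")
}

#' Unit tangent directions along a centerline
#'
#' Central differences in the interior, one-sided at the ends.
#'
#' @param cl a [centerline()].
#' @return n x 3 matrix of unit vectors.
#' @export
centerline_directions <- function(cl) {
  xyz <- cl_xyz(cl)
  n <- nrow(xyz)
  d <- matrix(0, n, 3)
  d[1, ] <- xyz[2, ] - xyz[1, ]
  d[n, ] <- xyz[n, ] - xyz[n - 1, ]
  if (n > 2L) d[2:(n - 1), ] <- xyz[3:n, , drop = FALSE] - xyz[1:(n - 2), , drop = FALSE]
  d / sqrt(rowSums(d^2))
}

#' Read a centerline from whitespace-delimited text
#'
#' One point per line, 3 or 4 numeric columns (`x y z [r]`), millimetres,
#' no header — the dialect used for CAT08-style reference centerlines.
#'
#' @param path file to read.
#' @param label optional branch label attached to the result.
#' @return A [centerline()].
#' @export
read_centerline <- function(path, label = "") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop("centerline file has fewer than 2 points: ", path, call. = FALSE)
  }
  toks <- strsplit(trimws(lines), "\\s+")
  ncol <- unique(lengths(toks))
  if (length(ncol) != 1L || !ncol %in% c(3L, 4L)) {
    stop("expected 3 or 4 whitespace-delimited columns in ", path, call. = FALSE)
  }
  vals <- suppressWarnings(lapply(toks, as.numeric))
  bad <- which(vapply(vals, function(v) any(is.na(v)), TRUE))
  if (length(bad)) {
    stop("non-numeric token at line ", bad[1], " of ", path, call. = FALSE)
  }
  centerline(do.call(rbind, vals), label = label)
}

#' Write a centerline as whitespace-delimited text
#'
#' Mirrors [read_centerline()]: one `x y z [r]` line per point, mm.
#'
#' @param cl a [centerline()].
#' @param path destination file.
#' @export
write_centerline <- function(cl, path) {
  stopifnot(inherits(cl, "centerline"))
  m <- as.matrix(cl[, intersect(c("x", "y", "z", "r"), names(cl))])
  lines <- apply(m, 1, function(row) paste(sprintf("%.9g", row), collapse = " "))
  writeLines(lines, path)
  invisible(NULL)
}

# ---- vessel trees ----------------------------------------------------------

#' A tree of linked centerlines
#'
#' Branches are [centerline()]s; `links` records where each child branch
#' attaches to its parent. Roots have no link row.
#'
#' @param branches list of [centerline()]s.
#' @param links tibble with integer columns `parent_branch`, `parent_point`,
#'   `child_branch` (1-based indices into `branches` / branch rows).
#' @return A `vessel_tree` object.
#' @export
vessel_tree <- function(branches = list(), links = NULL) {
  if (is.null(links)) {
    links <- tibble::tibble(parent_branch = integer(), parent_point = integer(),
                            child_branch = integer())
  }
  links <- tibble::as_tibble(links)
  stopifnot(all(c("parent_branch", "parent_point", "child_branch") %in% names(links)))
  nb <- length(branches)
  if (nrow(links)) {
    if (any(links$parent_branch < 1 | links$parent_branch > nb) ||
        any(links$child_branch < 1 | links$child_branch > nb)) {
      stop("tree links reference branches out of range", call. = FALSE)
    }
    if (anyDuplicated(links$child_branch)) {
      stop("each child branch may have only one parent", call. = FALSE)
    }
    # acyclicity: walking parents must terminate
    parent_of <- stats::setNames(links$parent_branch, links$child_branch)
    for (b in links$child_branch) {
      seen <- integer(); cur <- b
      while (!is.na(parent_of[as.character(cur)])) {
        if (cur %in% seen) stop("tree links contain a cycle", call. = FALSE)
        seen <- c(seen, cur)
        cur <- parent_of[[as.character(cur)]]
      }
    }
  }
  structure(list(branches = branches, links = links), class = "vessel_tree")
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree> %d branch(es), %d link(s)\n",
              length(x$branches), nrow(x$links)))
  for (i in seq_along(x$branches)) {
    cat(sprintf("  [%d] '%s': %d points, %.1f mm\n", i,
                attr(x$branches[[i]], "label") %||% "",
                nrow(x$branches[[i]]), centerline_length(x$branches[[i]])))
  }
  invisible(x)
}

#' All tree points as one tibble
#'
#' @param tree a [vessel_tree()].
#' @return tibble with columns `branch`, `x`, `y`, `z` and `r` when present.
#' @export
tree_points <- function(tree) {
  dplyr::bind_rows(lapply(seq_along(tree$branches), function(i) {
    b <- tibble::as_tibble(tree$branches[[i]])
    b$branch <- i
    b
  }))
}

#' Write / read a vessel tree as a directory of centerline files
#'
#' `write_tree()` emits `branch_01.txt`, `branch_02.txt`, ... plus a
#' `links.txt` manifest (three integer columns: parent branch, parent point,
#' child branch). `read_tree()` reverses it.
#'
#' @param tree a [vessel_tree()].
#' @param dir destination / source directory.
#' @export
write_tree <- function(tree, dir) {
  stopifnot(inherits(tree, "vessel_tree"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(tree$branches)) {
    write_centerline(tree$branches[[i]],
                     file.path(dir, sprintf("branch_%02d.txt", i)))
  }
  lk <- tree$links
  writeLines(
    c("# parent_branch parent_point child_branch",
      sprintf("%d %d %d", lk$parent_branch, lk$parent_point, lk$child_branch)),
    file.path(dir, "links.txt"))
  invisible(NULL)
}

#' @rdname write_tree
#' @export
read_tree <- function(dir) {
  files <- sort(list.files(dir, pattern = "^branch_\\d+\\.txt$", full.names = TRUE))
  if (!length(files)) stop("no branch files in ", dir, call. = FALSE)
  branches <- lapply(files, read_centerline)
  lk_path <- file.path(dir, "links.txt")
  links <- NULL
  if (file.exists(lk_path)) {
    lines <- readLines(lk_path, warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines)) {
      m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.integer))
      links <- tibble::tibble(parent_branch = m[, 1], parent_point = m[, 2],
                              child_branch = m[, 3])
    }
  }
  vessel_tree(branches, links)
}

#' Root-to-distal paths of a vessel tree
#'
#' Concatenates each branch with its ancestor chain (each parent up to the
#' attachment point), yielding one full ostium-to-distal centerline per
#' branch — the form in which reference vessels are usually annotated
#' (e.g. main vessels plus a named side branch), and the input from which
#' the direction-change prior is learned: a path crossing a bifurcation
#' contributes the branch turn to the angle statistics.
#'
#' @param tree a [vessel_tree()].
#' @return list of [centerline()]s, one per branch.
#' @export
tree_paths <- function(tree) {
  nb <- length(tree$branches)
  if (!nb) return(list())
  lk <- tree$links
  children <- unique(lk$child_branch)
  lapply(seq_len(nb), function(b) {
    rows <- tibble::as_tibble(tree$branches[[b]])
    cur <- b
    while (cur %in% children) {
      row <- lk[lk$child_branch == cur, ]
      par <- tibble::as_tibble(tree$branches[[row$parent_branch]])
      rows <- dplyr::bind_rows(par[seq_len(row$parent_point), ], rows)
      cur <- row$parent_branch
    }
    centerline(rows, label = sprintf("path_to_%d", b))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
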