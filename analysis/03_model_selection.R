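#!/usr/bin/env Rscript
# Stage 3: choose the number of trajectory groups.
#
# Fits censored-normal trajectory models for G = 1..6 and tabulates AIC,
# BIC (on observations and on children), minimum APPA and OCC, minimum
# modal group size, and the child-level 2-fold cross-validated mean
# distance. The CV curve is the primary guide: the number of groups is the
# point where it stops improving while all groups stay adequate
# (APPA > 0.7, OCC > 5).

library(sporttraj)

seed <- 20240901
data_dir <- "results/data"
out <- "results"
panel <- read.csv(file.path(data_dir, "monthly_panel.csv"))

sel <- selection_table(panel, G_range = 1:6, cv_k = 2, seed = seed,
                       n_starts = 2, max_iter = 300, tol = 1e-4)
chosen <- choose_group_count(sel)

write.csv(sel$table, file.path(out, "selection_table.csv"),
          row.names = FALSE)
saveRDS(sel$fits[[as.character(chosen)]],
        file.path(data_dir, "chosen_fit.rds"))
jsonlite::write_json(list(chosen_G = chosen, seed = seed),
                     file.path(out, "chosen_model.json"),
                     auto_unbox = TRUE, digits = NA)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  g <- ggplot2::ggplot(sel$table, ggplot2::aes(G, cv_2)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Number of groups",
                  y = "CV mean distance (sessions/week)",
                  title = "Cross-validated distance vs number of groups")
  ggplot2::ggsave(file.path(out, "figure_cv_distance.pdf"), g,
                  width = 5, height = 3.5)
}

print(as.data.frame(sel$table), digits = 4)
cat("\nChosen number of groups:", chosen, "\n")
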