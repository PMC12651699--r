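"""Independent all-point-interpolated AP@0.5 reference, used as a
cross-language check of the R implementation. Reads scenes from a JSON file
(argv[1]) and prints one AP per scene as a JSON array.

Each scene: {"class_id": c, "preds": [...], "truths": [...]} where each box
record has x_min, y_min, x_max, y_max, label, score (half-open pixel
coordinates). Matching: predictions of the class in descending score order
greedily claim the unmatched same-class truth with the highest IoU >= 0.5.
"""
import json
import sys

import numpy as np


def iou(a, b):
    iw = max(0.0, min(a[2], b[2]) - max(a[0], b[0]))
    ih = max(0.0, min(a[3], b[3]) - max(a[1], b[1]))
    inter = iw * ih
    area_a = (a[2] - a[0]) * (a[3] - a[1])
    area_b = (b[2] - b[0]) * (b[3] - b[1])
    return inter / (area_a + area_b - inter)


def box(rec):
    return (rec["x_min"], rec["y_min"], rec["x_max"], rec["y_max"])


def ap50(preds, truths, class_id):
    t = [box(r) for r in truths if r["label"] == class_id]
    if not t:
        return None
    p = [r for r in preds if r["label"] == class_id]
    p.sort(key=lambda r: -r["score"])
    taken = np.zeros(len(t), dtype=bool)
    tp = np.zeros(len(p), dtype=bool)
    for i, rec in enumerate(p):
        ious = np.array([iou(box(rec), tb) for tb in t]) if t else np.array([])
        ious[taken] = -1.0
        j = int(np.argmax(ious)) if ious.size else -1
        if j >= 0 and ious[j] >= 0.5:
            taken[j] = True
            tp[i] = True
    if not tp.any():
        return 0.0
    rec_curve = np.cumsum(tp) / len(t)
    prec_curve = np.cumsum(tp) / np.arange(1, len(p) + 1)
    # precision envelope (all-point interpolation)
    env = np.maximum.accumulate(prec_curve[::-1])[::-1]
    prev = np.concatenate(([0.0], rec_curve[:-1]))
    return float(np.sum((rec_curve - prev) * env))


def main():
    with open(sys.argv[1]) as fh:
        scenes = json.load(fh)
    out = [ap50(s["preds"], s["truths"], s["class_id"]) for s in scenes]
    print(json.dumps(out))


if __name__ == "__main__":
    main()
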