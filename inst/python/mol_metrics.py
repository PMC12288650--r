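"""Per-molecule drug-likeness (QED) and synthetic accessibility (Ertl SA).

Reads SMILES from stdin, one per line, and writes a TSV line per input:
    <qed>\t<sa_raw>\t<heavy_atoms>
with "NA" for unparsable molecules. Order matches the input.
"""
import os
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import QED, RDConfig

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402

RDLogger.DisableLog("rdApp.*")


def main():
    out = []
    for line in sys.stdin:
        smi = line.strip()
        if not smi:
            continue
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append("NA\tNA\tNA")
            continue
        out.append("%.10g\t%.10g\t%d" % (
            QED.qed(mol), sascorer.calculateScore(mol), mol.GetNumHeavyAtoms()))
    sys.stdout.write("\n".join(out) + "\n")


if __name__ == "__main__":
    main()
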