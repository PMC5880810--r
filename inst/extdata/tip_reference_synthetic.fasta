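>FaTIP_ref_synthetic
SEPDEKDSVLVVIVVFIFVIFFLVVLIVFIVVLLKGGPTRSKNNTEQEKTGDESEVIVLVVLVVHFFFLL
LFFLFLILIFFSGGHVNPAVTFDTLDQGGVIVIFVLLILFFVLVLAVIAILLLVVVNPSREQQPTSGSQV
FFILFVIVITLLLFLIVLFIFILLVDDRPKTTNDITFLIILILIIILVIIVVVIPLFGASMNPARAFGDA
QTVFFVIIHLFYWLVPVVVFFVILFLLLIINERTPKQKDETQPRNNETGPQTDQRKQDDGEPNRGGEQQE
DDDEEEKQGDEQSET
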