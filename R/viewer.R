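#' Write a self-contained HTML viewer for a map document
#'
#' Produces a single static HTML file embedding the map JSON and a small
#' script that renders the two facing hierarchies as nested columns
#' (domains left, topics right), with hover details, click-to-select
#' recolouring against the opposite side, a term search box and the year
#' histogram when present.  The viewer is a best-effort convenience; the
#' exported JSON ([map_export()], [write_map_json()]) is the stable
#' interface.
#'
#' @param map A `map_document` from [map_export()].
#' @param path Output HTML file.
#' @return Invisibly, `path`.
#' @export
write_map_html <- function(map, path) {
  json <- as.character(jsonlite::toJSON(unclass(map), auto_unbox = TRUE,
                                        digits = NA, null = "null"))
  html <- paste0('<!DOCTYPE html>
<html><head><meta charset="utf-8"><title>Domain-topic map</title>
<style>
body{font-family:sans-serif;margin:0;display:flex;height:100vh}
#left,#right{flex:1;overflow:auto;padding:8px}
#mid{width:280px;border-left:1px solid #ccc;border-right:1px solid #ccc;
     padding:8px;overflow:auto;font-size:12px}
.blk{border:1px solid #fff;cursor:pointer;font-size:10px;
     overflow:hidden;white-space:nowrap;padding-left:2px}
.lvl{display:inline-block;vertical-align:top;width:110px}
input{width:95%}
</style></head><body>
<div id="left"></div>
<div id="mid"><h3>Domain-topic map</h3>
<input id="q" placeholder="search term..."><div id="info"></div>
<div id="hist"></div></div>
<div id="right"></div>
<script>
var MAP = ', json, ';
function levels(root){var out=[];(function w(n,d){(out[d]=out[d]||[]).push(n);
  (n.children||[]).forEach(function(c){w(c,d+1)})})(root,0);return out}
function col(rel,red){var v=Math.round(255*(1-0.85*rel));
  return red?"rgb(255,"+v+","+v+")":"rgb("+v+","+v+",255)"}
function render(){
  ["left","right"].forEach(function(side){
    var root=side==="left"?MAP.domains:MAP.topics;
    var el=document.getElementById(side);el.innerHTML="";
    levels(root).forEach(function(lv){
      var c=document.createElement("div");c.className="lvl";
      var tot=lv.reduce(function(a,b){return a+b.volume},0);
      lv.forEach(function(b){
        var d=document.createElement("div");d.className="blk";
        d.style.height=Math.max(12,600*b.volume/tot)+"px";
        d.style.background=col(b.relevance,side==="left");
        d.textContent=b.label;d.title=b.label+" volume="+b.volume+
          " relevance="+b.relevance.toFixed(3);
        d.onclick=function(){show(b)};
        c.appendChild(d)});
      el.appendChild(c)})});
  if(MAP.histogram){var h=document.getElementById("hist");
    h.innerHTML="<h4>Documents per year</h4>";
    var mx=Math.max.apply(null,MAP.histogram.n_documents);
    MAP.histogram.year.forEach(function(y,i){
      var n=MAP.histogram.n_documents[i];
      h.innerHTML+="<div>"+y+" <span style=\'display:inline-block;"+
        "background:#888;height:8px;width:"+
        Math.round(150*n/mx)+"px\'></span> "+n+"</div>"})}}
function show(b){var el=document.getElementById("info");
  el.innerHTML="<b>"+b.label+"</b><br>level "+b.level+
    "<br>volume "+b.volume+"<br>relevance "+b.relevance.toFixed(4);
  var docs=MAP.documents&&MAP.documents[b.label];
  if(docs){el.innerHTML+="<br><i>"+docs.length+" documents</i><br>"+
    docs.slice(0,20).join("<br>")}}
document.getElementById("q").addEventListener("change",function(e){
  var t=MAP.term_index[e.target.value.trim()];
  var el=document.getElementById("info");
  el.innerHTML=t?("term belongs to topic <b>"+t+"</b>"):"term not found"});
render();
</script></body></html>')
  writeLines(html, path, useBytes = TRUE)
  invisible(path)
}
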